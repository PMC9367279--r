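---
title: "Methods: thermal indices, exposure features and dark-cutting risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal indices, exposure features and dark-cutting risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkcut)
```

## The problem

Dark cutting (DC) is the classification of a beef carcass whose ultimate
loin pH, measured 12–48 h post-mortem, is at or above 5.7. The proximate
cause is depleted muscle glycogen at slaughter, so anything that stresses
cattle or suppresses intake in the weeks before exit — handling, disease,
heat load, hormonal treatment — can raise DC risk. `darkcut` implements an
analysis pipeline for feedlot-level DC risk: thermal indices from on-site
weather stations, per-animal climatic exposure over the week before feedlot
departure, merged feedlot/abattoir records, and logistic risk models.

## Thermal indices

Weather stations record ambient temperature $T_A$ (°C), relative humidity
$RH$ (%), solar radiation $SR$ (W/m²), wind speed $WS$ (m/s) and rainfall
(mm) every 15 minutes.

**Black globe temperature.** The heat-load index needs the black globe
temperature, which these stations do not measure. We estimate it with the
predictor published alongside the HLI equations,
$$BGT = 1.33\,T_A - 2.65\sqrt{T_A} + 3.21\log_{10}(SR + 1) + 3.5,$$
exposed as a pluggable function (`index_series(bgt_fun = ...)`) so a
locally calibrated estimator can be substituted. Two domain choices the
source formula leaves open: for $T_A < 0$ (winter nights at inland
feedlots) the square root is extended as
$\mathrm{sign}(T_A)\sqrt{|T_A|}$, keeping the predictor continuous through
zero; temperatures below −60 °C are rejected as data errors.

**THI.** The Thom-derived temperature–humidity index is
$$THI = 0.8\,T_A + \frac{RH}{100}(T_A - 14.4) + 46.4 .$$
At $T_A = 14.4$ °C the humidity term vanishes, a property the tests
exploit. Some statements of this index describe the temperature input as a
wet- or dew-point temperature; the operational convention here, as in the
feedlot heat-load literature, is ambient (dry-bulb) temperature, and the
tension is documented rather than resolved.

**HLI.** The heat-load index has two branches around a black-globe switch
point of 25 °C:
$$HLI_{BGT>25} = 8.62 + 0.38\,RH + 1.55\,BGT - 0.5\,WS + e^{2.4 - WS},$$
$$HLI_{BGT<25} = 10.66 + 0.28\,RH + 1.3\,BGT - WS.$$
The published branches are disjoint at exactly 25 °C; we assign the switch
point to the linear branch. The branches do not meet — the discontinuity is
about one HLI unit for typical humidity/wind — and we document it rather
than smooth it, since any smoothing would be an invention with no published
counterpart.

**AHL.** The accumulated heat load is a running balance for the standard
reference animal (healthy, unshaded black steer under 100 days on feed):
starting at zero, each observation adds $(HLI - 86)/M$ when HLI exceeds the
upper threshold 86, subtracts $(77 - HLI)/M$ when HLI is below the lower
threshold 77, does nothing in the thermoneutral band, and is clamped at
zero after every step; $M$ is the number of observations per hour (4 for
15-minute data). The published conditional notation for this balance is
internally inconsistent as printed (it would subtract without a floor); the
clamped-balance reading implemented here is the behaviour its source
describes — cattle dissipate heat below the lower threshold but can never
bank a negative heat load. The implementation is verified against an
independent step-by-step trace oracle on a thousand random series.

**QC.** `qc_and_resample()` aligns a record onto its regular grid, masks
physically implausible values ($T_A \notin [-20, 55]$ °C,
$RH \notin [0, 100]$, $WS > 60$ m/s, $SR > 1500$ W/m², negative rain — all
configurable), linearly interpolates gaps up to 6 h, fills rain in short
gaps with zero (an absent tipping-bucket interval is no evidence of rain),
and reports everything: masked counts, interpolated counts, and gaps too
long to bridge, which downstream exposure windows then see as reduced
coverage. No attempt is made to diagnose subtler station faults
(drift, icing, shading); records a user distrusts should be excluded
explicitly, which the pipeline supports per feedlot.

## Exposure features

For each animal the exposure window is the half-open 7 days before its
feedlot departure, $[exit - 7\,\mathrm{d}, exit)$, ending at the recorded
exit time when one exists and at midnight of the exit date otherwise
(the choice is configurable; nothing in the source design pins it down).
Within the window each variable is first reduced to per-calendar-day
statistics (station-local midnight boundaries) and these are averaged
across days: the `mean`, `min`, `max` covariates are means of daily means,
minima and maxima, and `range` is the mean daily max−min. This matches the
heat-load literature's daily-summary convention and keeps the four
covariate families on comparable scales; a `global` mode computing
whole-window statistics is available. Rain enters as the 7-day total in mm.

Two threshold-duration covariates summarise HLI: the hours per day spent at
HLI ≥ 86 (total duration over the window divided by 7), and the number of
days with at least 6 h at HLI ≤ 70 — hot-load exposure and cold-recovery
days respectively. The hours-per-day form is used for the ≥ 86 covariate
because the reported effect size ("per one hour longer per day") is only
interpretable on that scale; the day-count variant (`days_hli_ge86`) is
also computed and stored.

Windows with coverage below 0.8 (configurable) yield a flagged missing
exposure rather than a biased summary. Animals at feedlots whose climate
record is excluded stay in the production models and drop out of the
climatic ones, mirroring the study design in which three of seven stations
were unusable.

## Records

Feedlot and carcass records merge by the NLIS identifier (inner join;
unmatched ids on both sides are reported, never silently dropped; duplicate
ids are an error). Derived fields follow their operational definitions:
DOF is the whole-day calendar difference exit − induction; ADG is
(exit − entry weight)/DOF, undefined at DOF = 0 (counted and excluded);
transport time is arrival minus exit, with an overnight rule — when only
clock times are available, a negative difference gains 24 h once and
anything beyond 24 h is rejected.

The DC threshold is boundary-inclusive: pH exactly 5.7 is non-compliant.
Incidence tables support two denominator conventions — DC over all
carcasses (the default, standard incidence) and DC over compliant
carcasses, which some industry summaries use; both are labelled explicitly
because the two conventions appear mixed in published summary tables of
this kind.

## Risk models

**Base model.** An ordinary logistic GLM for the DC indicator with fixed
effects: days on feed per 10-day increment, HGP (reference: untreated), sex
(reference: female), abattoir (reference: A) and feedlot (reference: A).
Morbidity is available as an optional term, off by default to match the
usual base-model presentation. Estimation is by IRLS (deviance tolerance
10⁻¹⁰), Wald standard errors from the inverse observed information, and
Wald z p-values. No multiple-testing adjustment is applied, matching the
analysis this package operationalises. When the consignment structure makes
a column linearly dependent — with the default composition, feedlots D and
E supply only abattoir A, so the feedlot E indicator equals a combination
of the intercept, abattoir and feedlot D columns — `build_design()` detects
it by QR and drops it with a record, rather than failing: this is exactly
the aliasing pattern the reported base model exhibits (it carries no
feedlot E row). Coefficients with standardised magnitude above 15 flag
probable separation.

**Climatic models.** Three mixed logistic model families, each with sex
and HGP fixed and crossed random intercepts for feedlot and slaughter date
(treated as independent; nothing suggests nesting), estimated by
Laplace-approximate ML through `lme4::glmer`. Family 1 uses the raw
weather covariates (SR, WS, rain, RH, $T_A$), family 2 replaces RH and
$T_A$ with THI, family 3 uses rain and HLI summaries; the split exists
because THI and HLI are functions of the raw variables and cannot coexist
with them in one model. Each family comes in variants selecting the daily
summary (mean/range/max/min; SR and WS stay at daily means except in the
max variant, following the tabulated layouts; family 3's variants are
mean, max, hours ≥ 86 and cold days ≤ 70). Rain total always enters. The
degenerate case is contractual: when every estimated random-effect
variance is at the zero boundary, the fixed effects must agree with the
plain logistic fit to 10⁻⁴, and the test suite enforces it.

`run_model_suite()` fits the base model plus the twelve climatic variants
(13 fits); per-fit failures become skip notices so one degenerate variant
cannot abort a run.

## The synthetic generator

Because the underlying industry data are not public, the package ships a
generator whose defaults define the reference study conditions, and every
empirical claim in this document is one the tests or the acceptance script
actually compute on its output.

*Weather*: per station-year at 15-minute cadence — annual mean 18 °C with
an 8 °C southern-hemisphere seasonal sinusoid (peak mid-January) and a
6 °C diurnal sinusoid (peak 15:00), AR(1) noise (coefficient 0.7,
stationary sd 1.5 °C); humidity 65% baseline moving opposite the
within-day temperature excursion at 2.5 %/°C, clamped to [5, 100];
daylight half-sine solar radiation peaking at 950 W/m² with daily cloud
attenuation drawn from [0.5, 1]; gamma wind (shape 2, scale 1.5 m/s); wet
days with probability 0.25 and exponential totals (mean 6 mm) spread over
a handful of intervals. These are field-plausible values for inland
Australian feedlot country chosen once; generated series always pass QC
with nothing masked. What the generator does **not** emulate: station
faults, spatial correlation between feedlots, heatwave persistence beyond
AR(1), and seasonal daylight-length variation — so passing tests validate
the pipeline's arithmetic and inference, not meteorology.

*Herd*: seven feedlots with the study-profile composition — herd shares,
HGP and male proportions, and per-feedlot DOF means/SDs taken from the
study's internally consistent composition table; feedlots D and E consign
to abattoir A, B and G to abattoir B, A and F to abattoir C, and C splits
21.1%/78.9% between B and C. Morbidity prevalence (5%) and mean transport
times are not tabulated per feedlot in the source and carry plausible
defaults. Where the source's tables disagree with each other about which
feedlot label carries which profile, the generator follows the one
internally consistent column set.

*Outcomes*: $\mathrm{logit}\,P(DC) = X\beta_{true} + u_{feedlot} +
v_{date}$, with $\beta_{true}$ defaulting to the logs of the reported
base-model odds ratios (intercept 0.197; DOF-per-10-days 1.02; HGP 2.29;
steer 1.14; abattoir B/C 3.66/0.88; feedlots B/C/D/F/G
1.27/0.95/2.21/0.51/0.97; morbidity 1.34; feedlot E 0, matching its
aliasing) plus mean-model climatic effects (SR 0.997, WS 0.961, rain
1.0129, $T_A$ 1.0315) that contribute when exposures are supplied. The
random-intercept standard deviations default to zero, making the default
truth exactly the fixed-effects base model; set them positive to exercise
the GLMM path. Ultimate pH is drawn from truncated normals on either side
of 5.7 (DC: mean 5.9, sd 0.15; compliant: mean 5.5, sd 0.06) so
`classify_dc()` reproduces the generated flag exactly.

One caveat stated openly: the printed intercept combined with the printed
slopes and the real covariate mix implies a baseline risk far above the
observed ~2.8% incidence — the published coefficient table is not
internally consistent with the published incidence tables. The defaults
keep the printed values because parameter recovery is invariant to
prevalence; for prevalence-realistic simulations replace the intercept
with `log(0.03/0.97)` in `true_coefficients`.

*Recovery harness*: `recovery_report()` repeats simulate→fit over seeded
replicates and reports per-term bias and 95% Wald coverage. The problem
sizes used by the shipped tests — a single full-scale replicate at
~140,000 animals and 40 replicates at 20,000 for coverage, plus a
5,000-animal end-to-end pipeline run — were chosen as the smallest designs
that make the recovery checks statistically meaningful at their stated
tolerances.

## Numerical choices and degenerate inputs

* IRLS tolerance 10⁻¹⁰ on deviance, 100 iterations; GLMM by Laplace (the
  `lme4` default), with singular fits allowed and reported through
  `ranef_var` rather than warned about.
* Empty weather series, empty windows, zero-animal feedlots and empty
  result sets all produce empty, well-typed outputs rather than errors;
  genuinely invalid inputs (out-of-range pH or RH, non-monotone
  timestamps, duplicate ids, exit before induction) fail fast with the
  offending value named.
* Ties: HLI at BGT exactly 25 takes the linear branch; pH exactly 5.7 is
  DC; a window point exactly at the exit instant is excluded (half-open
  window).
* Seeds: every generator takes an explicit seed; the same seed reproduces
  byte-identical CSV output.

## Limitations

The climatic covariates are station-level, not pen-level microclimate; no
shade adjustment, panting-score physiology or wet-bulb psychrometrics are
modelled. Transport-leg and lairage climate are out of scope. The models
report coefficients, not post hoc pairwise contrasts. And since the
synthetic generator defines the only data the package can be validated
against without the proprietary records, its simplifications bound what a
green test suite demonstrates about real feedlot data.
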