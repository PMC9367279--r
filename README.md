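# darkcut

Risk modelling of **dark cutting** in grain-fed beef cattle. A carcass is a
dark cutter (DC) when its ultimate loin pH at grading is **≥ 5.7** — dark,
high-pH meat caused by depleted muscle glycogen at slaughter, which attracts
a per-kilogram price deduction. `darkcut` is for livestock scientists and
feedlot analysts who want to quantify how production factors (days on feed,
hormone growth promotants, sex, feedlot, abattoir, morbidity) and the
climatic conditions of the week before feedlot departure drive DC risk.

The package covers the full pipeline:

* **Thermal indices** from 15-minute weather-station records: black globe
  temperature (BGT), the temperature–humidity index

  `THI = 0.8·T_A + (RH/100)·(T_A − 14.4) + 46.4`,

  the two-branch heat-load index

  `HLI_{BGT>25} = 8.62 + 0.38·RH + 1.55·BGT − 0.5·WS + e^(2.4−WS)`
  `HLI_{BGT<25} = 10.66 + 0.28·RH + 1.3·BGT − WS`,

  and the accumulated heat load (AHL), a non-negative balance that gains
  `(HLI − 86)/M` per observation above the upper threshold, decays below 77,
  and is clamped at zero (`M` = observations per hour).
* **Exposure features**: per-animal summaries (daily mean/min/max/range,
  rain total, HLI threshold durations) of the 7 days before feedlot exit.
* **Record handling**: feedlot and carcass CSVs merged by NLIS identifier,
  derived fields (DOF, ADG, transport time), incidence tables and crude
  odds ratios.
* **Risk models**: the base production-factor logistic model
  `logit P(DC) = β₀ + β_DOF·(DOF/10) + β_HGP + β_sex + abattoir + feedlot`
  and three climatic mixed logistic models (random intercepts for feedlot
  and slaughter date; Laplace approximation via `lme4`), reported as odds
  ratios with Wald 95% intervals.
* **Synthetic data**: a weather/herd/outcome generator with known ground
  truth, so every stage is testable end-to-end and the fitting machinery
  can be validated by parameter recovery.

## Worked example

Thermal indices for a hot summer hour (15-minute cadence, `M = 4`):

```r
library(darkcut)
obs <- tibble::tibble(
  timestamp = as.POSIXct("2018-01-05 12:00", tz = "UTC") + 900 * (0:3),
  ta = c(33, 34, 35, 34), rh = c(40, 38, 35, 37),
  sr = c(900, 950, 980, 940), ws = c(1.2, 1.0, 0.8, 1.1), rain = 0)
index_series(obs)[, c("bgt", "thi", "hli", "ahl")]
#>     bgt   thi   hli   ahl
#> 1 41.65 80.24 91.10 1.275
#> 2 42.83 81.05 93.00 3.025
#> 3 43.98 81.61 94.64 5.183
#> 4 42.81 80.85 92.16 6.723
```

Every HLI value exceeds the upper threshold of 86, so the heat-load balance
accumulates `(HLI − 86)/4` at each step and reaches 6.7 units in one hour.

Simulate a 20,000-head herd with the default ground-truth coefficients and
recover them with the base model:

```r
library(dplyr)
cfg <- herd_sim_config(n_total = 20000, seed = 1)
sim <- simulate_herd(cfg)
animals <- derive_fields(sim$animals)
rec <- inner_join(animals, sim$carcass_base, by = "nlis")
carc <- simulate_outcomes(rec, NULL, cfg)
records <- merge_records(animals, carc[, c("nlis", "abattoir", "kill_date",
                                           "ph_u", "loin_temp", "hump_height")])$records
d <- build_design(records, model_spec("base"))
fit_logistic(d$y, d$X)
#> <darkcut_fit> logistic fit: n = 20000, logLik = -12908.6
#>         term estimate       se     or ci_low ci_high         p
#>  (Intercept) -1.63534 0.100250 0.1949 0.1601  0.2372 8.031e-60
#>        dof10  0.02065 0.003586 1.0209 1.0137  1.0281 8.455e-09
#>       hgpyes  0.79344 0.047282 2.2110 2.0153  2.4257 3.359e-63
#>         sexM  0.23841 0.041984 1.2692 1.1690  1.3781 1.359e-08
#>    abattoirB  1.39877 0.145319 4.0502 3.0464  5.3849 6.238e-22
#>    ...
```

The fitted odds ratios sit on top of the generating values (HGP 2.29,
DOF-per-10-days 1.02, abattoir B 3.66, …): an animal treated with a hormone
growth promotant has roughly 2.2 times the odds of cutting dark, and each
extra 10 days on feed multiplies the odds by about 1.02. The feedlot E
indicator is aliased with the abattoir structure (feedlots D and E consign
exclusively to abattoir A) and is dropped automatically —
`build_design()$aliased` records it.

For a complete run — simulated weather stations, exposure windows, the base
model and all twelve climatic variants —

```r
simulate_study("study", herd = herd_sim_config(n_total = 5000), seed = 7)
run_pipeline(list(weather_dir = "study",
                  animals = "study/animals.csv",
                  carcasses = "study/carcasses.csv",
                  out_dir = "out"))
```

writes thermal-index and QC files per feedlot, per-animal exposures, 13
model coefficient tables and incidence summaries under `out/`.

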