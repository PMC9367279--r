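#' Configuration for the synthetic weather generator
#'
#' Parameters of a stochastic 15-minute weather process emulating an
#' Australian feedlot station year: a southern-hemisphere seasonal sinusoid
#' (temperature peak in mid-January), a diurnal sinusoid peaking
#' mid-afternoon, AR(1) temperature noise, humidity anti-correlated with the
#' within-day temperature excursion, a half-sine daylight solar-radiation
#' curve with daily cloud attenuation, gamma-distributed wind speed, and
#' wet-day Bernoulli rainfall with exponential daily totals.
#'
#' @param start_date First day of the series (default the study-year start,
#'   1 September 2017).
#' @param n_days Number of days (default 365).
#' @param interval_minutes Sampling cadence (default 15).
#' @param ta_mean_annual,ta_seasonal_amplitude,ta_diurnal_amplitude Annual
#'   mean and sinusoid amplitudes, degrees C.
#' @param ta_ar1,ta_noise_sd AR(1) coefficient and stationary standard
#'   deviation of the temperature noise.
#' @param rh_base,rh_ta_slope Humidity baseline (%) and its decrease per
#'   degree of within-day warming.
#' @param sr_peak Clear-sky solar-radiation peak, W/m^2.
#' @param ws_shape,ws_scale Gamma parameters for wind speed (m/s).
#' @param rain_wet_day_prob,rain_mean_mm Wet-day probability and mean wet-day
#'   total (mm).
#' @param seed Optional integer seed; fixed seed gives byte-identical output.
#' @return List of class `weather_sim_config`.
#' @export
weather_sim_config <- function(start_date = as.Date("2017-09-01"),
                               n_days = 365, interval_minutes = 15,
                               ta_mean_annual = 18, ta_seasonal_amplitude = 8,
                               ta_diurnal_amplitude = 6,
                               ta_ar1 = 0.7, ta_noise_sd = 1.5,
                               rh_base = 65, rh_ta_slope = 2.5,
                               sr_peak = 950, ws_shape = 2, ws_scale = 1.5,
                               rain_wet_day_prob = 0.25, rain_mean_mm = 6,
                               seed = NULL) {
  stopifnot(ta_seasonal_amplitude >= 0, ta_diurnal_amplitude >= 0,
            ta_noise_sd >= 0, rain_wet_day_prob >= 0, rain_wet_day_prob <= 1,
            n_days >= 1)
  structure(as.list(environment()), class = "weather_sim_config")
}

#' Simulate a weather-station series
#'
#' @param config A [weather_sim_config()].
#' @return Tibble of observations (`timestamp`, `ta`, `rh`, `sr`, `ws`,
#'   `rain`) that passes [qc_and_resample()] with no masked points.
#' @export
simulate_weather <- function(config = weather_sim_config()) {
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  step <- cfg$interval_minutes * 60
  n <- cfg$n_days * 24 * 60 / cfg$interval_minutes
  t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  ts <- t0 + step * (0:(n - 1))

  doy <- as.numeric(format(ts, "%j")) + as.numeric(format(ts, "%H")) / 24
  hour <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  # southern hemisphere: warmest around 15 January (doy 15)
  seasonal <- cfg$ta_seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  diurnal <- cfg$ta_diurnal_amplitude * cos(2 * pi * (hour - 15) / 24)

  eps <- numeric(n)
  if (cfg$ta_noise_sd > 0) {
    innov_sd <- cfg$ta_noise_sd * sqrt(1 - cfg$ta_ar1^2)
    z <- stats::rnorm(n, 0, innov_sd)
    eps[1] <- stats::rnorm(1, 0, cfg$ta_noise_sd)
    for (i in 2:n) eps[i] <- cfg$ta_ar1 * eps[i - 1] + z[i]
  }
  ta <- cfg$ta_mean_annual + seasonal + diurnal + eps
  ta <- pmin(pmax(ta, -20), 55)

  day <- as.Date(ts, tz = "UTC")
  day_mean <- stats::ave(ta, day, FUN = mean)
  rh <- pmin(pmax(cfg$rh_base - cfg$rh_ta_slope * (ta - day_mean), 5), 100)

  n_day <- length(unique(day))
  cloud <- stats::runif(n_day, 0.5, 1)[match(day, unique(day))]
  sun <- pmax(0, sin(pi * (hour - 6) / 12))
  sun[hour < 6 | hour > 18] <- 0
  sr <- pmin(cfg$sr_peak * sun * cloud, 1500)

  ws <- pmin(stats::rgamma(n, shape = cfg$ws_shape, scale = cfg$ws_scale), 60)

  rain <- numeric(n)
  wet <- stats::runif(n_day) < cfg$rain_wet_day_prob
  totals <- stats::rexp(n_day, 1 / cfg$rain_mean_mm) * wet
  for (d in which(wet)) {
    ix <- which(day == unique(day)[d])
    k <- min(length(ix), sample(4:12, 1))
    at <- sample(ix, k)
    w <- stats::runif(k)
    rain[at] <- rain[at] + totals[d] * w / sum(w)
  }

  tibble::tibble(timestamp = ts, ta = ta, rh = rh, sr = sr, ws = ws,
                 rain = rain)
}

#' Default per-feedlot composition of the synthetic herd
#'
#' Seven feedlots consigning to three abattoirs with the study's marginal
#' composition: herd sizes, HGP-treatment and male proportions, days-on-feed
#' means/SDs and consignment routes (feedlot C splits between two abattoirs;
#' all others supply a single one). Morbidity prevalence and mean transport
#' times are not tabulated at feedlot level in the source material and carry
#' field-plausible defaults.
#'
#' @return Tibble, one row per feedlot.
#' @export
default_feedlots <- function() {
  tibble::tibble(
    feedlot = LETTERS[1:7],
    n_animals = c(7472L, 18546L, 18989L, 62349L, 6082L, 8237L, 19147L),
    hgp_prob = c(1, 0, 0.837, 0.884, 0.944, 1, 0.519),
    male_prob = c(0.034, 0.866, 0.254, 0.838, 0.999, 0.423, 0.927),
    morbidity_prob = rep(0.05, 7),
    dof_mean = c(82.2, 285, 96.3, 105, 98.2, 61, 136),
    dof_sd = c(17, 92, 36.3, 25.3, 7.07, 3.05, 38.2),
    transport_hours_mean = c(3, 7, 2, 3, 6, 4, 3),
    abattoir = c("C", "B", "C", "A", "A", "C", "B"),
    abattoir_alt = c(NA, NA, "B", NA, NA, NA, NA),
    abattoir_alt_prob = c(0, 0, 0.211, 0, 0, 0, 0)
  )
}

#' Ground-truth coefficients for the outcome generator
#'
#' Named log-odds, keyed exactly as the design-matrix columns of the base
#' model plus the mean-variant climatic terms. Defaults are the logs of the
#' reported base-model odds ratios (intercept 0.197, DOF-per-10-days 1.02,
#' HGP 2.29, steer 1.14, abattoir B 3.66, abattoir C 0.88, feedlots B/C/D/F/G
#' 1.27/0.95/2.21/0.51/0.97, morbidity 1.34) and of the mean-model climatic
#' odds ratios (solar radiation 0.997 per W/m^2, wind speed 0.961 per m/s,
#' rain 1.0129 per mm, ambient temperature 1.0315 per degree C). The feedlot
#' E effect is zero: with feedlots D and E consigning exclusively to one
#' abattoir it is not separately identifiable and the reported model carries
#' no such term.
#'
#' @return Named numeric vector of log-odds coefficients.
#' @export
default_true_coefficients <- function() {
  c(`(Intercept)` = log(0.197),
    dof10 = log(1.02),
    hgpyes = log(2.29),
    sexM = log(1.14),
    morbidityyes = log(1.34),
    abattoirB = log(3.66),
    abattoirC = log(0.88),
    feedlotB = log(1.27),
    feedlotC = log(0.95),
    feedlotD = log(2.21),
    feedlotE = 0,
    feedlotF = log(0.51),
    feedlotG = log(0.97),
    sr_mean = log(0.997),
    ws_mean = log(0.961),
    rain_total_7 = log(1.0129),
    ta_mean = log(1.0315))
}

#' Configuration for the synthetic herd generator
#'
#' @param feedlots Per-feedlot composition table; see [default_feedlots()].
#' @param n_total If given, feedlot herd sizes are scaled proportionally to
#'   this total (useful for fast test-scale cohorts).
#' @param true_coefficients Named log-odds for the outcome generator; see
#'   [default_true_coefficients()].
#' @param random_sd_feedlot,random_sd_date Standard deviations of the
#'   feedlot and slaughter-date random intercepts (default 0: the truth is
#'   exactly the fixed-effects base model).
#' @param start_date,n_days Study window the exit dates are spread over.
#' @param window_days Pre-departure exposure window length (exit dates are
#'   kept at least this far after `start_date`).
#' @param seed Optional integer seed.
#' @return List of class `herd_sim_config`.
#' @export
herd_sim_config <- function(feedlots = default_feedlots(), n_total = NULL,
                            true_coefficients = default_true_coefficients(),
                            random_sd_feedlot = 0, random_sd_date = 0,
                            start_date = as.Date("2017-09-01"), n_days = 365,
                            window_days = 7, seed = NULL) {
  stopifnot(all(feedlots$n_animals >= 0),
            all(feedlots$hgp_prob >= 0 & feedlots$hgp_prob <= 1),
            all(feedlots$male_prob >= 0 & feedlots$male_prob <= 1),
            random_sd_feedlot >= 0, random_sd_date >= 0)
  if (!is.null(n_total)) {
    scale <- n_total / sum(feedlots$n_animals)
    feedlots$n_animals <- pmax(0L, as.integer(round(feedlots$n_animals * scale)))
  }
  structure(as.list(environment())[setdiff(names(as.list(environment())),
                                           c("scale", "n_total"))],
            class = "herd_sim_config")
}

#' Simulate feedlot animal records (and optionally their climate exposures)
#'
#' Draws a herd with the configured per-feedlot composition: exit dates
#' uniform over the study window, days on feed from a truncated normal, sex,
#' HGP and morbidity Bernoulli, entry weights and daily gains normal, and
#' abattoir consignment per the feedlot's route. When `weather` (a named
#' list of weather tibbles, one per feedlot; `NULL` entries allowed for
#' excluded stations) is supplied, thermal indices and 7-day pre-departure
#' exposures are computed through the real index and exposure code path.
#'
#' @param config A [herd_sim_config()].
#' @param weather Optional named list of weather observation tibbles.
#' @param hli An [hli_params()] for the index computation.
#' @return List with `animals`, `carcass_base` (abattoir, kill date, loin
#'   temperature, hump height; ultimate pH is filled by
#'   [simulate_outcomes()]) and `exposures` (or `NULL`).
#' @export
simulate_herd <- function(config = herd_sim_config(), weather = NULL,
                          hli = hli_params()) {
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fl <- cfg$feedlots
  end_date <- cfg$start_date + cfg$n_days - 1

  rows <- vector("list", nrow(fl))
  id0 <- 0L
  for (i in seq_len(nrow(fl))) {
    f <- fl[i, ]
    n <- f$n_animals
    if (n == 0L) next
    exit_date <- cfg$start_date + cfg$window_days +
      floor(stats::runif(n) * as.numeric(end_date - cfg$start_date - cfg$window_days + 1))
    dof <- pmax(8L, as.integer(round(stats::rnorm(n, f$dof_mean, f$dof_sd))))
    entry_weight <- round(stats::rnorm(n, 380, 40), 1)
    adg <- pmax(0.5, stats::rnorm(n, 1.8, 0.3))
    sex <- ifelse(stats::runif(n) < f$male_prob, "M", "F")
    hgp <- ifelse(stats::runif(n) < f$hgp_prob, "yes", "no")
    morbidity <- ifelse(stats::runif(n) < f$morbidity_prob, "yes", "no")
    abattoir <- if (!is.na(f$abattoir_alt) && f$abattoir_alt_prob > 0) {
      ifelse(stats::runif(n) < f$abattoir_alt_prob, f$abattoir_alt, f$abattoir)
    } else rep(f$abattoir, n)
    transport <- pmax(0.25, stats::rnorm(n, f$transport_hours_mean, 1))
    exit_time <- as.POSIXct(paste(exit_date, "07:00:00"), tz = "UTC")
    rows[[i]] <- tibble::tibble(
      nlis = sprintf("NLIS%07d", id0 + seq_len(n)),
      lot = paste0(f$feedlot, format(exit_date, "%Y%m")),
      feedlot = f$feedlot,
      induction_date = exit_date - dof,
      exit_date = exit_date,
      entry_weight = entry_weight,
      exit_weight = round(entry_weight + adg * dof, 1),
      sex = sex, hgp = hgp, morbidity = morbidity,
      exit_time = exit_time,
      arrival_time = exit_time + round(transport * 3600),
      abattoir = abattoir,
      kill_date = exit_date + 1L,
      loin_temp = round(stats::rnorm(n, 6, 1), 1),
      hump_height = pmax(0, 5 * round(stats::rnorm(n, 13, 4)))
    )
    id0 <- id0 + n
  }
  animals_full <- dplyr::bind_rows(rows)
  animals <- animals_full[, c("nlis", "lot", "feedlot", "induction_date",
                              "exit_date", "entry_weight", "exit_weight",
                              "sex", "hgp", "morbidity", "exit_time",
                              "arrival_time")]
  carcass_base <- animals_full[, c("nlis", "abattoir", "kill_date",
                                   "loin_temp", "hump_height")]

  exposures <- NULL
  if (!is.null(weather)) {
    series <- lapply(weather, function(w) {
      if (is.null(w)) return(NULL)
      index_series(w, params = hli)
    })
    exposures <- attach_exposures(animals, series,
                                  window_days = cfg$window_days)
  }
  list(animals = animals, carcass_base = carcass_base, exposures = exposures)
}

#' Simulate dark-cutting outcomes and ultimate pH
#'
#' Draws the DC indicator from the generative logistic model
#' \eqn{\eta = X\beta_{true} + u_{feedlot} + v_{kill date}} with the
#' configured true coefficients and random-intercept standard deviations,
#' then fills ultimate pH from truncated normals consistent with the flag:
#' above 5.7 (mean 5.9, sd 0.15) for dark cutters, below 5.7 (mean 5.5,
#' sd 0.06) otherwise — so [classify_dc()] reproduces the simulated flag
#' exactly. Climatic terms in the truth vector contribute only for animals
#' whose exposure row is present and complete.
#'
#' @param records Animal records joined with their carcass base rows
#'   (must carry `dof` or `induction_date`/`exit_date`, `hgp`, `sex`,
#'   `morbidity`, `feedlot`, `abattoir`, `kill_date`).
#' @param exposures Optional exposure tibble from [attach_exposures()].
#' @param config A [herd_sim_config()] supplying `true_coefficients` and the
#'   random-effect standard deviations.
#' @return Carcass tibble (`nlis`, `abattoir`, `kill_date`, `ph_u`,
#'   `loin_temp`, `hump_height`) plus the true `dc` flag and linear
#'   predictor `eta`.
#' @export
simulate_outcomes <- function(records, exposures = NULL,
                              config = herd_sim_config()) {
  b <- config$true_coefficients
  known <- c("(Intercept)", "dof10", "hgpyes", "sexM", "morbidityyes",
             paste0("abattoir", LETTERS), paste0("feedlot", LETTERS))
  climate_names <- setdiff(names(b), known)
  if (!is.null(exposures)) {
    missing_terms <- setdiff(climate_names,
                             c(names(exposures), "exposure_missing"))
    if (length(missing_terms) > 0L) {
      stop("true coefficient(s) with no matching covariate: ",
           paste(missing_terms, collapse = ", "),
           "; expected design-column names like `hgpyes`, `sexM`, ",
           "`feedlotB`, `sr_mean`", call. = FALSE)
    }
  }
  n <- nrow(records)
  dof <- if ("dof" %in% names(records)) records$dof else {
    as.integer(records$exit_date - records$induction_date)
  }
  bval <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  eta <- rep(bval("(Intercept)"), n) +
    bval("dof10") * dof / 10 +
    bval("hgpyes") * (records$hgp == "yes") +
    bval("sexM") * (records$sex == "M") +
    bval("morbidityyes") * (records$morbidity == "yes")
  for (lv in unique(records$abattoir)) {
    eta <- eta + bval(paste0("abattoir", lv)) * (records$abattoir == lv)
  }
  for (lv in unique(records$feedlot)) {
    eta <- eta + bval(paste0("feedlot", lv)) * (records$feedlot == lv)
  }
  if (!is.null(exposures) && length(climate_names) > 0L) {
    ex <- exposures[match(records$nlis, exposures$nlis), , drop = FALSE]
    ok <- !is.na(ex$exposure_missing) & !ex$exposure_missing
    for (nm in climate_names) {
      v <- ex[[nm]]
      contrib <- ifelse(ok & !is.na(v), v, 0)
      eta <- eta + b[[nm]] * contrib
    }
  }
  if (config$random_sd_feedlot > 0) {
    lv <- unique(records$feedlot)
    u <- stats::setNames(stats::rnorm(length(lv), 0, config$random_sd_feedlot), lv)
    eta <- eta + u[as.character(records$feedlot)]
  }
  if (config$random_sd_date > 0) {
    lv <- unique(as.character(records$kill_date))
    v <- stats::setNames(stats::rnorm(length(lv), 0, config$random_sd_date), lv)
    eta <- eta + v[as.character(records$kill_date)]
  }

  dc <- stats::runif(n) < stats::plogis(eta)
  ph_u <- numeric(n)
  ph_u[dc] <- rtrunc_norm(sum(dc), 5.9, 0.15, lower = 5.7, upper = 7.5)
  ph_u[!dc] <- rtrunc_norm(sum(!dc), 5.5, 0.06, lower = 4.5, upper = 5.7 - 1e-9)
  ph_u <- round(ph_u, 3)
  ph_u[dc] <- pmax(ph_u[dc], 5.7)
  ph_u[!dc] <- pmin(ph_u[!dc], 5.69)

  tibble::tibble(
    nlis = records$nlis,
    abattoir = records$abattoir,
    kill_date = records$kill_date,
    ph_u = ph_u,
    loin_temp = records$loin_temp,
    hump_height = records$hump_height,
    dc = dc,
    eta = eta
  )
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Parameter-recovery harness
#'
#' Repeats simulate-herd, simulate-outcomes and model fitting, then reports
#' per-term bias and 95% Wald-interval coverage of the generating
#' coefficients. With the generator's defaults this doubles as a
#' plausibility check that the fitted effect sizes reproduce the reported
#' odds ratios.
#'
#' @param n_replicates Number of seeded replicates.
#' @param config A [herd_sim_config()]; `config$seed` is ignored in favour
#'   of `seed + replicate`.
#' @param spec The [model_spec()] to fit (default the base model).
#' @param seed Base seed.
#' @return Tibble with one row per estimated term: `term`, `true_or`,
#'   `mean_or`, `bias_log`, `coverage`, `n_replicates`.
#' @export
recovery_report <- function(n_replicates, config = herd_sim_config(),
                            spec = model_spec("base"), seed = 1) {
  stopifnot(n_replicates >= 1)
  truth <- config$true_coefficients
  per_rep <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seed + r
    sim <- simulate_herd(cfg)
    animals <- derive_fields(sim$animals)
    records <- dplyr::inner_join(animals, sim$carcass_base, by = "nlis")
    carcasses <- simulate_outcomes(records, NULL, cfg)
    records <- merge_records(animals,
                             carcasses[, c("nlis", "abattoir", "kill_date",
                                           "ph_u", "loin_temp", "hump_height")])$records
    d <- build_design(records, spec)
    fit <- if (length(d$groups) > 0) {
      fit_mixed_logistic(d$y, d$X, d$groups)
    } else {
      fit_logistic(d$y, d$X)
    }
    ct <- fit$coefficients
    ct$replicate <- r
    per_rep[[r]] <- ct
  }
  all <- dplyr::bind_rows(per_rep)
  all$true <- truth[all$term]
  all <- all[!is.na(all$true), , drop = FALSE]
  all |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      true_or = exp(.data$true[1]),
      mean_or = exp(mean(.data$estimate)),
      bias_log = mean(.data$estimate - .data$true),
      coverage = mean(.data$true >= .data$estimate - 1.96 * .data$se &
                        .data$true <= .data$estimate + 1.96 * .data$se),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}
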