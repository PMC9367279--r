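#' Thermal-index parameters for the heat-load balance
#'
#' Bundles the thresholds and sampling cadence used by [compute_hli()] and
#' [accumulate_heat_load()]. The defaults describe the standard reference
#' animal (an unshaded black steer under 100 days on feed): heat is dissipated
#' below an HLI of 77 and gained above 86, with weather sampled four times an
#' hour (15-minute observations).
#'
#' @param lower_threshold HLI value below which cattle dissipate heat
#'   (default 77).
#' @param upper_threshold HLI value above which cattle gain heat (default 86).
#' @param bgt_switch Black globe temperature (degrees C) at which the HLI
#'   equation changes branch (default 25).
#' @param measures_per_hour Number of observations per hour, `M`; 4 for
#'   15-minute data, 6 for 10-minute data.
#' @return A list of class `hli_params`.
#' @examples
#' hli_params()
#' hli_params(measures_per_hour = 6) # 10-minute stations
#' @export
hli_params <- function(lower_threshold = 77, upper_threshold = 86,
                       bgt_switch = 25, measures_per_hour = 4) {
  stopifnot(is.numeric(lower_threshold), is.numeric(upper_threshold))
  if (lower_threshold >= upper_threshold) {
    stop("`lower_threshold` must be strictly below `upper_threshold`",
         call. = FALSE)
  }
  if (measures_per_hour < 1) {
    stop("`measures_per_hour` must be at least 1", call. = FALSE)
  }
  structure(
    list(lower_threshold = lower_threshold,
         upper_threshold = upper_threshold,
         bgt_switch = bgt_switch,
         measures_per_hour = measures_per_hour),
    class = "hli_params"
  )
}

#' Estimate black globe temperature from air temperature and solar radiation
#'
#' Weather stations in this pipeline record no black-globe sensor, so BGT is
#' estimated from ambient temperature and solar radiation with the predictor
#' published alongside the heat-load index:
#' \deqn{BGT = 1.33 T_A - 2.65 \sqrt{T_A} + 3.21 \log_{10}(SR + 1) + 3.5}
#' For sub-zero temperatures (winter nights at inland feedlots) the square
#' root is extended as \eqn{\mathrm{sign}(T_A)\sqrt{|T_A|}}, since the
#' predictor's source does not define that domain.
#'
#' The estimator is pluggable: pass a different `fun` to
#' [index_series()] if a locally calibrated predictor is preferred.
#'
#' @param ta Ambient temperature, degrees C.
#' @param sr Solar radiation, W/m^2 (non-negative).
#' @return Black globe temperature, degrees C.
#' @examples
#' estimate_bgt(25, 0)    # 23.5
#' estimate_bgt(25, 800)  # radiation warms the globe
#' @export
estimate_bgt <- function(ta, sr) {
  check_numeric(ta, "ta")
  check_numeric(sr, "sr")
  if (any(ta < -60, na.rm = TRUE)) {
    stop("ambient temperature below -60 C is not physically plausible",
         call. = FALSE)
  }
  if (any(sr < 0, na.rm = TRUE)) {
    stop("solar radiation must be non-negative", call. = FALSE)
  }
  signed_sqrt <- sign(ta) * sqrt(abs(ta))
  1.33 * ta - 2.65 * signed_sqrt + 3.21 * log10(sr + 1) + 3.5
}

#' Temperature-humidity index
#'
#' Thom-derived THI combining ambient temperature and relative humidity:
#' \deqn{THI = 0.8 T_A + \frac{RH}{100}(T_A - 14.4) + 46.4}
#' At 14.4 degrees C the humidity term vanishes, so THI is independent of RH
#' there.
#'
#' @param ta Ambient temperature, degrees C.
#' @param rh Relative humidity, percent (0-100).
#' @return THI, unitless.
#' @examples
#' compute_thi(25, 50) # 71.7
#' @export
compute_thi <- function(ta, rh) {
  check_numeric(ta, "ta")
  check_rh(rh)
  0.8 * ta + (rh / 100) * (ta - 14.4) + 46.4
}

#' Heat-load index
#'
#' Two-branch cattle heat-stress index. Above the black-globe switch point
#' (25 degrees C) the nonlinear form applies:
#' \deqn{HLI_{BGT>25} = 8.62 + 0.38 RH + 1.55 BGT - 0.5 WS + e^{2.4 - WS}}
#' and at or below it the linear form:
#' \deqn{HLI_{BGT<25} = 10.66 + 0.28 RH + 1.3 BGT - WS}
#' A BGT of exactly 25 is assigned to the linear branch; the two branches do
#' not meet, leaving a discontinuity of roughly one HLI unit at the switch
#' point, which is documented rather than smoothed away.
#'
#' @param bgt Black globe temperature, degrees C.
#' @param rh Relative humidity, percent.
#' @param ws Wind speed, m/s (non-negative).
#' @param params An [hli_params()] object (supplies the branch switch point).
#' @return HLI, unitless.
#' @examples
#' compute_hli(30, 50, 2) # hot branch
#' compute_hli(20, 40, 1) # 46.86
#' @export
compute_hli <- function(bgt, rh, ws, params = hli_params()) {
  check_numeric(bgt, "bgt")
  check_rh(rh)
  check_numeric(ws, "ws")
  if (any(ws < 0, na.rm = TRUE)) {
    stop("wind speed must be non-negative", call. = FALSE)
  }
  hot <- 8.62 + 0.38 * rh + 1.55 * bgt - 0.5 * ws + exp(2.4 - ws)
  cool <- 10.66 + 0.28 * rh + 1.3 * bgt - ws
  ifelse(bgt > params$bgt_switch, hot, cool)
}

#' Accumulated heat load
#'
#' Running heat-load balance for the reference animal. Starting from zero, at
#' each observation the balance gains \eqn{(HLI - 86)/M} when HLI exceeds the
#' upper threshold, decays by \eqn{(77 - HLI)/M} when HLI is below the lower
#' threshold, and is unchanged in the thermoneutral band between the two; it
#' is clamped at zero after every step so the animal never carries a negative
#' heat debt. `M` is the number of observations per hour, so a full hour above
#' threshold accumulates the hourly exceedance.
#'
#' @param hli Numeric vector of HLI values in time order, evenly sampled at
#'   `params$measures_per_hour` observations per hour.
#' @param params An [hli_params()] object.
#' @return Numeric vector of AHL values, same length as `hli`, all `>= 0`.
#'   `NA` HLI values leave the balance unchanged and yield `NA` for that step's
#'   output.
#' @examples
#' accumulate_heat_load(rep(90, 4)) # one hour at HLI 90 -> 4 units
#' @export
accumulate_heat_load <- function(hli, params = hli_params()) {
  if (length(hli) == 0L) return(numeric(0))
  check_numeric(hli, "hli")
  m <- params$measures_per_hour
  up <- params$upper_threshold
  lo <- params$lower_threshold
  out <- numeric(length(hli))
  bal <- 0
  for (i in seq_along(hli)) {
    h <- hli[i]
    if (is.na(h)) {
      out[i] <- NA_real_
      next
    }
    if (h > up) {
      bal <- bal + (h - up) / m
    } else if (h < lo) {
      bal <- bal + (h - lo) / m
    }
    if (bal < 0) bal <- 0
    out[i] <- bal
  }
  out
}

#' Compute the full thermal-index series for a weather record
#'
#' Vectorised composition of [estimate_bgt()], [compute_thi()],
#' [compute_hli()] and [accumulate_heat_load()] over a validated table of
#' weather observations.
#'
#' @param observations A data frame with columns `timestamp` (POSIXct,
#'   strictly increasing), `ta`, `rh`, `sr`, `ws` and optionally `rain`.
#' @param params An [hli_params()] object.
#' @param bgt_fun Black-globe estimator, a function of `(ta, sr)`; defaults to
#'   [estimate_bgt()].
#' @param keep_weather Keep the input weather columns alongside the indices
#'   (default `TRUE`; downstream exposure summaries need them).
#' @return A tibble with columns `timestamp`, (weather columns,) `bgt`, `thi`,
#'   `hli`, `ahl`.
#' @examples
#' obs <- tibble::tibble(
#'   timestamp = as.POSIXct("2018-01-01 12:00", tz = "UTC") + 900 * (0:3),
#'   ta = 25, rh = 50, sr = 0, ws = 2, rain = 0
#' )
#' index_series(obs)
#' @export
index_series <- function(observations, params = hli_params(),
                         bgt_fun = estimate_bgt, keep_weather = TRUE) {
  obs <- validate_observations(observations)
  if (nrow(obs) == 0L) {
    out <- tibble::tibble(timestamp = obs$timestamp,
                          bgt = numeric(0), thi = numeric(0),
                          hli = numeric(0), ahl = numeric(0))
    return(out)
  }
  bgt <- bgt_fun(obs$ta, obs$sr)
  thi <- compute_thi(obs$ta, obs$rh)
  hli <- compute_hli(bgt, obs$rh, obs$ws, params)
  ahl <- accumulate_heat_load(hli, params)
  out <- if (keep_weather) obs else obs["timestamp"]
  out$bgt <- bgt
  out$thi <- thi
  out$hli <- hli
  out$ahl <- ahl
  tibble::as_tibble(out)
}

#' Default physical plausibility ranges for weather QC
#'
#' @return Named list of `c(min, max)` ranges for `ta`, `rh`, `ws`, `sr`.
#' @export
qc_ranges <- function() {
  list(ta = c(-20, 55), rh = c(0, 100), ws = c(0, 60), sr = c(0, 1500))
}

#' Quality-control and regularise a weather series
#'
#' Aligns a station record onto a regular grid, masks physically implausible
#' values, linearly interpolates short gaps, and reports everything it did.
#' Rain in short gaps is filled with zero (a missing tipping-bucket interval
#' carries no evidence of rain); longer gaps are left missing and reported so
#' exposure windows overlapping them can be flagged downstream.
#'
#' @param observations Weather data frame (`timestamp`, `ta`, `rh`, `sr`,
#'   `ws`, `rain`).
#' @param expected_interval Sampling interval in minutes (default 15).
#' @param max_gap Longest gap, in hours, that may be bridged by linear
#'   interpolation (default 6).
#' @param ranges Plausibility ranges, as from [qc_ranges()].
#' @return A list with `observations` (the cleaned, regular tibble) and
#'   `report`, a list with counts of masked and interpolated points per
#'   variable, points still missing, and a table of gaps longer than
#'   `max_gap`.
#' @export
qc_and_resample <- function(observations, expected_interval = 15,
                            max_gap = 6, ranges = qc_ranges()) {
  obs <- validate_observations(observations, check_ranges = FALSE)
  if (nrow(obs) == 0L) {
    return(list(observations = obs,
                report = list(n_input = 0L, n_grid = 0L,
                              masked = integer(0), interpolated = integer(0),
                              missing_after = integer(0),
                              long_gaps = tibble::tibble())))
  }
  step <- expected_interval * 60
  grid <- tibble::tibble(
    timestamp = seq(min(obs$timestamp), max(obs$timestamp), by = step)
  )
  full <- dplyr::left_join(grid, obs, by = "timestamp")

  vars <- c("ta", "rh", "ws", "sr")
  masked <- integer(0)
  for (v in vars) {
    rng <- ranges[[v]]
    bad <- !is.na(full[[v]]) & (full[[v]] < rng[1] | full[[v]] > rng[2])
    masked[v] <- sum(bad)
    full[[v]][bad] <- NA_real_
  }
  bad_rain <- !is.na(full$rain) & full$rain < 0
  masked["rain"] <- sum(bad_rain)
  full$rain[bad_rain] <- NA_real_

  maxgap_pts <- floor(max_gap * 60 / expected_interval)
  interpolated <- integer(0)
  for (v in vars) {
    before <- is.na(full[[v]])
    full[[v]] <- zoo::na.approx(full[[v]], x = as.numeric(full$timestamp),
                                maxgap = maxgap_pts, na.rm = FALSE)
    interpolated[v] <- sum(before & !is.na(full[[v]]))
  }
  # rain: short gaps carry no evidence of rain -> 0; long gaps stay NA
  rain_na <- is.na(full$rain)
  if (any(rain_na)) {
    runs <- rle(rain_na)
    fillable <- rep(runs$values & runs$lengths <= maxgap_pts, runs$lengths)
    interpolated["rain"] <- sum(fillable)
    full$rain[fillable] <- 0
  } else {
    interpolated["rain"] <- 0L
  }

  missing_after <- vapply(full[c(vars, "rain")],
                          function(x) sum(is.na(x)), integer(1))

  gap_na <- is.na(full$ta)
  long_gaps <- tibble::tibble(start = as.POSIXct(character(0), tz = "UTC"),
                              end = as.POSIXct(character(0), tz = "UTC"),
                              n_points = integer(0))
  if (any(gap_na)) {
    runs <- rle(gap_na)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values & runs$lengths > maxgap_pts
    long_gaps <- tibble::tibble(
      start = full$timestamp[starts[keep]],
      end = full$timestamp[ends[keep]],
      n_points = runs$lengths[keep]
    )
  }

  list(
    observations = tibble::as_tibble(full),
    report = list(
      n_input = nrow(obs),
      n_grid = nrow(grid),
      masked = masked,
      interpolated = interpolated,
      missing_after = missing_after,
      long_gaps = long_gaps
    )
  )
}

# --- internal validation helpers ------------------------------------------

check_numeric <- function(x, name) {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  }
  invisible(x)
}

check_rh <- function(rh) {
  check_numeric(rh, "rh")
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    stop("relative humidity must lie in [0, 100]", call. = FALSE)
  }
  invisible(rh)
}

validate_observations <- function(observations, check_ranges = TRUE) {
  need <- c("timestamp", "ta", "rh", "sr", "ws")
  missing_cols <- setdiff(need, names(observations))
  if (length(missing_cols) > 0L) {
    stop("weather observations lack columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- tibble::as_tibble(observations)
  if (!("rain" %in% names(obs))) obs$rain <- 0
  if (!inherits(obs$timestamp, "POSIXct")) {
    obs$timestamp <- as.POSIXct(obs$timestamp, tz = "UTC")
  }
  if (nrow(obs) > 1L && any(diff(as.numeric(obs$timestamp)) <= 0)) {
    bad <- which(diff(as.numeric(obs$timestamp)) <= 0)[1] + 1L
    stop("timestamps must be strictly increasing; violation at row ", bad,
         " (", format(obs$timestamp[bad]), ")", call. = FALSE)
  }
  if (check_ranges) {
    if (any(obs$rh < 0 | obs$rh > 100, na.rm = TRUE)) {
      bad <- which(obs$rh < 0 | obs$rh > 100)[1]
      stop("relative humidity outside [0, 100] at ",
           format(obs$timestamp[bad]), call. = FALSE)
    }
    for (v in c("sr", "ws", "rain")) {
      if (any(obs[[v]] < 0, na.rm = TRUE)) {
        bad <- which(obs[[v]] < 0)[1]
        stop(sprintf("`%s` must be non-negative; violation at %s", v,
                     format(obs$timestamp[bad])), call. = FALSE)
      }
    }
  }
  obs
}
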