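#' Slice a thermal-index series to the pre-departure exposure window
#'
#' Returns the observations in the half-open window
#' `[exit - window_days, exit)` — by default the 7 days before the animal left
#' the feedlot — together with the fraction of the expected observations
#' actually present, so partial station coverage can be detected.
#'
#' @param series A thermal-index tibble from [index_series()] (or any table
#'   with a POSIXct `timestamp` column at a regular cadence).
#' @param exit_datetime POSIXct departure time.
#' @param window_days Length of the window in days (default 7).
#' @param interval_minutes Sampling interval; inferred from the series when
#'   `NULL`.
#' @return The sliced tibble with attribute `coverage` in `[0, 1]`. A slice
#'   with zero rows signals missing exposure for that animal.
#' @export
exposure_window <- function(series, exit_datetime, window_days = 7,
                            interval_minutes = NULL) {
  stopifnot(inherits(exit_datetime, "POSIXct"))
  start <- exit_datetime - window_days * 86400
  keep <- series$timestamp >= start & series$timestamp < exit_datetime
  slice <- series[keep, , drop = FALSE]
  if (is.null(interval_minutes)) {
    interval_minutes <- infer_interval(series$timestamp)
  }
  expected <- window_days * 24 * 60 / interval_minutes
  # points whose weather is entirely missing (long station gaps) do not count
  present <- nrow(slice)
  if (present > 0L && "ta" %in% names(slice)) {
    present <- sum(!is.na(slice$ta))
  }
  attr(slice, "coverage") <- min(1, present / expected)
  attr(slice, "interval_minutes") <- interval_minutes
  slice
}

#' Summarise an exposure window into per-animal climatic covariates
#'
#' Computes the covariates used by the climatic risk models from one animal's
#' pre-departure window. For each of ambient temperature, relative humidity,
#' solar radiation, wind speed, THI and HLI, the window is first reduced to
#' daily statistics (per station-local calendar day) and those are averaged
#' across the days in the window: `*_mean` is the mean of daily means,
#' `*_max` the mean of daily maxima, `*_min` the mean of daily minima and
#' `*_range` the mean of daily (max - min). This follows the heat-load
#' literature's daily-summary convention; set `mode = "global"` for plain
#' whole-window statistics instead. Also computed:
#'
#' * `rain_total_7`: total rainfall (mm) over the window;
#' * `hours_hli_ge86_per_day`: hours per day with HLI at or above 86
#'   (total duration / `window_days`);
#' * `days_hli_ge86`: number of days with any HLI at or above 86;
#' * `days_hli_le70_ge6h`: number of days with at least 6 h of HLI at or
#'   below 70 (cold-side recovery days).
#'
#' @param slice A window slice from [exposure_window()], carrying the weather
#'   columns and `thi`/`hli`.
#' @param min_coverage Minimum acceptable coverage fraction (default 0.8);
#'   below it a classed error (`darkcut_missing_exposure`) is raised.
#' @param mode `"daily"` (default) or `"global"` aggregation.
#' @param window_days Window length used for the per-day normalisations.
#' @return One-row tibble of exposure covariates plus `coverage`.
#' @export
summarize_exposure <- function(slice, min_coverage = 0.8, mode = c("daily", "global"),
                               window_days = 7) {
  mode <- match.arg(mode)
  coverage <- attr(slice, "coverage")
  if (is.null(coverage)) coverage <- 1
  if (nrow(slice) == 0L || coverage < min_coverage) {
    stop(missing_exposure_condition(coverage))
  }
  interval <- attr(slice, "interval_minutes")
  if (is.null(interval)) interval <- infer_interval(slice$timestamp)

  vars <- intersect(c("ta", "rh", "sr", "ws", "thi", "hli"), names(slice))
  day <- as.Date(slice$timestamp, tz = attr(slice$timestamp, "tzone") %||% "UTC")

  out <- list()
  for (v in vars) {
    x <- slice[[v]]
    if (mode == "daily") {
      dm <- tapply(x, day, mean, na.rm = TRUE)
      dmin <- tapply(x, day, min, na.rm = TRUE)
      dmax <- tapply(x, day, max, na.rm = TRUE)
      out[[paste0(v, "_mean")]] <- mean(dm, na.rm = TRUE)
      out[[paste0(v, "_min")]] <- mean(dmin, na.rm = TRUE)
      out[[paste0(v, "_max")]] <- mean(dmax, na.rm = TRUE)
      out[[paste0(v, "_range")]] <- mean(dmax - dmin, na.rm = TRUE)
    } else {
      out[[paste0(v, "_mean")]] <- mean(x, na.rm = TRUE)
      out[[paste0(v, "_min")]] <- min(x, na.rm = TRUE)
      out[[paste0(v, "_max")]] <- max(x, na.rm = TRUE)
      out[[paste0(v, "_range")]] <- out[[paste0(v, "_max")]] - out[[paste0(v, "_min")]]
    }
  }
  out$rain_total_7 <- if ("rain" %in% names(slice)) {
    sum(slice$rain, na.rm = TRUE)
  } else NA_real_

  if ("hli" %in% names(slice)) {
    hrs_per_point <- interval / 60
    hot <- !is.na(slice$hli) & slice$hli >= 86
    out$hours_hli_ge86_per_day <- sum(hot) * hrs_per_point / window_days
    out$days_hli_ge86 <- length(unique(day[hot]))
    cold_hours <- tapply(!is.na(slice$hli) & slice$hli <= 70, day, sum)
    out$days_hli_le70_ge6h <- sum(cold_hours * hrs_per_point >= 6, na.rm = TRUE)
  }
  out$coverage <- coverage
  tibble::as_tibble(out)
}

#' Attach pre-departure climate exposures to animal records
#'
#' Computes one exposure row per animal from its feedlot's thermal-index
#' series. Feedlots whose climate record was excluded (supply `NULL` in
#' `series_by_feedlot`) yield rows flagged `exposure_missing` with a reason,
#' mirroring the analysis design in which feedlots with unusable station data
#' are kept in the production models but dropped from the climatic ones.
#' Feedlot labels absent from `series_by_feedlot` altogether are treated as a
#' data error.
#'
#' @param animals Animal records with `nlis`, `feedlot` and `exit_date`
#'   (and optionally `exit_time`, used as the window end when present).
#' @param series_by_feedlot Named list mapping feedlot label to an
#'   [index_series()] tibble, or `NULL` for feedlots without usable climate.
#' @param window_days,min_coverage,mode Passed to [exposure_window()] and
#'   [summarize_exposure()].
#' @return Tibble with `nlis`, `feedlot`, the exposure covariates,
#'   `exposure_missing` (logical) and `exposure_reason`.
#' @export
attach_exposures <- function(animals, series_by_feedlot, window_days = 7,
                             min_coverage = 0.8, mode = "daily") {
  unknown <- setdiff(unique(as.character(animals$feedlot)),
                     names(series_by_feedlot))
  if (length(unknown) > 0L) {
    stop("no climate series entry for feedlot(s): ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  exit_dt <- animal_exit_datetime(animals)
  key <- paste(animals$feedlot, format(exit_dt, "%Y-%m-%d %H:%M:%S"))
  idx <- match(key, unique(key))
  uniq <- !duplicated(key)

  summaries <- vector("list", sum(uniq))
  u_feedlot <- as.character(animals$feedlot[uniq])
  u_exit <- exit_dt[uniq]
  for (i in seq_along(summaries)) {
    series <- series_by_feedlot[[u_feedlot[i]]]
    if (is.null(series)) {
      summaries[[i]] <- missing_exposure_row("feedlot climate record excluded")
      next
    }
    slice <- exposure_window(series, u_exit[i], window_days = window_days)
    summaries[[i]] <- tryCatch(
      {
        s <- summarize_exposure(slice, min_coverage = min_coverage,
                                mode = mode, window_days = window_days)
        s$exposure_missing <- FALSE
        s$exposure_reason <- NA_character_
        s
      },
      darkcut_missing_exposure = function(e) {
        missing_exposure_row(conditionMessage(e))
      }
    )
  }
  res <- dplyr::bind_rows(summaries)[idx, , drop = FALSE]
  dplyr::bind_cols(
    tibble::tibble(nlis = animals$nlis, feedlot = animals$feedlot),
    res
  )
}

# --- helpers ---------------------------------------------------------------

animal_exit_datetime <- function(animals) {
  tz <- "UTC"
  if ("exit_time" %in% names(animals) && inherits(animals$exit_time, "POSIXct")) {
    dt <- animals$exit_time
    fill <- is.na(dt)
    if (any(fill)) {
      dt[fill] <- as.POSIXct(paste(animals$exit_date[fill], "00:00:00"), tz = tz)
    }
    return(dt)
  }
  as.POSIXct(paste(animals$exit_date, "00:00:00"), tz = tz)
}

infer_interval <- function(timestamps) {
  if (length(timestamps) < 2L) return(15)
  stats::median(diff(as.numeric(timestamps))) / 60
}

missing_exposure_condition <- function(coverage) {
  structure(
    class = c("darkcut_missing_exposure", "error", "condition"),
    list(message = sprintf("window coverage %.2f below required minimum",
                           coverage %||% 0),
         call = NULL)
  )
}

missing_exposure_row <- function(reason) {
  tibble::tibble(coverage = NA_real_, exposure_missing = TRUE,
                 exposure_reason = reason)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
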