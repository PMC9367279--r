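#' Build and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a named list. Unknown keys are rejected so a
#' typo cannot silently fall back to a default. Recognised keys:
#' `weather_dir`, `animals`, `carcasses`, `out_dir`, `excluded_feedlots`,
#' `hli` (a list of [hli_params()] overrides), `window_days`,
#' `min_coverage`, `mode`, `denominator`, `expected_interval`, `max_gap`,
#' `include_morbidity`, `seed`.
#'
#' @param config Path to a YAML file or a named list.
#' @return A validated `run_config` list with defaults filled.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    weather_dir = NULL, animals = NULL, carcasses = NULL, out_dir = NULL,
    excluded_feedlots = character(0),
    hli = list(), window_days = 7, min_coverage = 0.8, mode = "daily",
    denominator = "total", expected_interval = 15, max_gap = 6,
    include_morbidity = FALSE, seed = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  for (key in c("animals", "carcasses")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("configured `", key, "` file does not exist: ", cfg[[key]],
           call. = FALSE)
    }
  }
  if (!is.null(cfg$weather_dir) && !dir.exists(cfg$weather_dir)) {
    stop("configured `weather_dir` does not exist: ", cfg$weather_dir,
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full dark-cutting analysis pipeline
#'
#' Executes the stages indices -> merge -> features -> fit -> report on the
#' configured inputs, writing each stage's artifact under `out_dir` along
#' with a run manifest. A failure stops at the failing stage with an error
#' naming it.
#'
#' Expected inputs: `weather_dir` containing `weather_<feedlot>.csv` files,
#' plus `animals` and `carcasses` CSVs (see [read_animals()] and
#' [read_carcasses()] for the layouts).
#'
#' @param config A [run_config()] (or list/YAML path coercible to one).
#' @return Invisibly, a list with the merged `records`, the fitted `suite`,
#'   the rendered `tables` and the per-stage `counts`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.null(cfg$out_dir)) stop("`out_dir` must be configured", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hli <- do.call(hli_params, cfg$hli)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage `", name, "`: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- indices ------------------------------------------------------------
  series <- stage("indices", {
    if (is.null(cfg$weather_dir)) stop("`weather_dir` not configured")
    files <- list.files(cfg$weather_dir, pattern = "^weather_.*\\.csv$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("no weather_<feedlot>.csv files found in ",
                                  cfg$weather_dir)
    out <- list()
    for (f in files) {
      feedlot <- sub("^weather_(.*)\\.csv$", "\\1", basename(f))
      if (feedlot %in% cfg$excluded_feedlots) {
        out[feedlot] <- list(NULL)
        next
      }
      obs <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
      qc <- qc_and_resample(obs, expected_interval = cfg$expected_interval,
                            max_gap = cfg$max_gap)
      idx <- index_series(qc$observations, params = hli)
      readr::write_csv(idx[, c("timestamp", "bgt", "thi", "hli", "ahl")],
                       file.path(cfg$out_dir,
                                 paste0("indices_", feedlot, ".csv")))
      qc_plain <- qc$report
      qc_plain$long_gaps <- as.data.frame(qc_plain$long_gaps)
      jsonlite::write_json(qc_plain,
                           file.path(cfg$out_dir, paste0("qc_", feedlot, ".json")),
                           auto_unbox = TRUE, POSIXt = "ISO8601")
      out[[feedlot]] <- idx
      message("indices: feedlot ", feedlot, ", ", nrow(idx), " observations")
    }
    out
  })

  # -- merge --------------------------------------------------------------
  merged <- stage("merge", {
    animals <- derive_fields(read_animals(cfg$animals))
    carcasses <- read_carcasses(cfg$carcasses)
    m <- merge_records(animals, carcasses)
    message("merge: ", m$report$matched, " matched, ",
            m$report$n_unmatched_animals, "/",
            m$report$n_unmatched_carcasses, " unmatched")
    m
  })

  # -- features -----------------------------------------------------------
  records <- stage("features", {
    exposures <- attach_exposures(merged$records, series,
                                  window_days = cfg$window_days,
                                  min_coverage = cfg$min_coverage,
                                  mode = cfg$mode)
    readr::write_csv(exposures, file.path(cfg$out_dir, "exposures.csv"))
    rec <- dplyr::left_join(merged$records,
                            exposures[, setdiff(names(exposures), "feedlot")],
                            by = "nlis")
    readr::write_csv(rec, file.path(cfg$out_dir, "analysis.csv"))
    message("features: ", sum(!exposures$exposure_missing), " of ",
            nrow(exposures), " animals with climate exposure")
    rec
  })

  # -- fit ----------------------------------------------------------------
  suite <- stage("fit", {
    s <- run_model_suite(records,
                         default_model_specs(cfg$include_morbidity))
    message("fit: ", length(s$fits), " model(s) fitted, ",
            length(s$notices), " skipped")
    s
  })

  # -- report -------------------------------------------------------------
  tables <- stage("report", {
    tabs <- render_tables(suite, dir = cfg$out_dir)
    for (by in intersect(c("feedlot", "hgp", "sex"), names(records))) {
      for (den in c("total", "compliant")) {
        readr::write_csv(incidence_table(records, by, den),
                         file.path(cfg$out_dir,
                                   sprintf("incidence_%s_%s.csv", by, den)))
      }
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("darkcut")),
      r_version = R.version.string,
      inputs = list(animals = cfg$animals, carcasses = cfg$carcasses,
                    weather_dir = cfg$weather_dir),
      config = unclass(cfg)[c("excluded_feedlots", "window_days",
                              "min_coverage", "mode", "denominator",
                              "expected_interval", "max_gap",
                              "include_morbidity")],
      n_records = nrow(records),
      models_fitted = names(suite$fits),
      models_skipped = names(suite$notices)
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
    tabs
  })

  invisible(list(records = records, suite = suite, tables = tables,
                 counts = list(n_records = nrow(records),
                               n_fits = length(suite$fits))))
}

#' Render model results as coefficient tables
#'
#' Writes (and returns) one coefficient table per fitted model with the
#' fixed column order `term, estimate, se, or, ci_low, ci_high, p`, plus an
#' aligned plain-text rendering with odds ratios to four significant
#' figures.
#'
#' @param suite A `darkcut_suite` from [run_model_suite()] (or a single
#'   `darkcut_fit`).
#' @param dir Output directory; when `NULL` nothing is written.
#' @return Named list of coefficient tibbles.
#' @export
render_tables <- function(suite, dir = NULL) {
  fits <- if (inherits(suite, "darkcut_fit")) {
    stats::setNames(list(suite), suite$model %||% "model")
  } else suite$fits
  cols <- c("term", "estimate", "se", "or", "ci_low", "ci_high", "p")
  out <- list()
  for (nm in names(fits)) {
    tab <- fits[[nm]]$coefficients[, cols]
    out[[nm]] <- tab
    if (!is.null(dir)) {
      readr::write_csv(tab, file.path(dir, paste0("model_", nm, ".csv")))
      txt <- data.frame(
        term = format(tab$term),
        or = formatC(signif(tab$or, 4), format = "g"),
        ci = sprintf("%.4g-%.4g", tab$ci_low, tab$ci_high),
        p = formatC(tab$p, format = "g", digits = 3)
      )
      writeLines(
        c(sprintf("%-28s %10s %22s %10s", "term", "OR", "95% CI", "p"),
          sprintf("%-28s %10s %22s %10s", txt$term, txt$or, txt$ci, txt$p)),
        file.path(dir, paste0("model_", nm, ".txt"))
      )
    }
  }
  out
}

#' Write a complete synthetic study to disk
#'
#' Generates per-feedlot weather, the herd, and outcomes, and writes
#' `weather_<feedlot>.csv`, `animals.csv`, `carcasses.csv` and `truth.json`
#' (the generating parameters) — a self-contained input set for
#' [run_pipeline()].
#'
#' @param out_dir Output directory (created if needed).
#' @param herd A [herd_sim_config()].
#' @param weather A [weather_sim_config()] used as template for every
#'   feedlot's station (each receives a distinct derived seed).
#' @param seed Integer master seed.
#' @return Invisibly, a list with the written file paths and the truth.
#' @export
simulate_study <- function(out_dir, herd = herd_sim_config(),
                           weather = weather_sim_config(), seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feedlots <- herd$feedlots$feedlot
  weather_list <- list()
  for (i in seq_along(feedlots)) {
    wcfg <- weather
    wcfg$seed <- seed * 100 + i
    wcfg$start_date <- herd$start_date
    wcfg$n_days <- herd$n_days
    w <- simulate_weather(wcfg)
    weather_list[[feedlots[i]]] <- w
    readr::write_csv(w, file.path(out_dir,
                                  paste0("weather_", feedlots[i], ".csv")))
  }
  hcfg <- herd
  hcfg$seed <- seed
  sim <- simulate_herd(hcfg, weather = weather_list)
  animals <- derive_fields(sim$animals)
  records <- dplyr::inner_join(animals, sim$carcass_base, by = "nlis")
  carcasses <- simulate_outcomes(records, sim$exposures, hcfg)
  readr::write_csv(sim$animals, file.path(out_dir, "animals.csv"))
  readr::write_csv(carcasses[, c("nlis", "abattoir", "kill_date", "ph_u",
                                 "loin_temp", "hump_height")],
                   file.path(out_dir, "carcasses.csv"))
  truth <- list(
    seed = seed,
    true_coefficients = as.list(herd$true_coefficients),
    random_sd_feedlot = herd$random_sd_feedlot,
    random_sd_date = herd$random_sd_date,
    n_animals = nrow(sim$animals)
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, truth = truth,
                 files = list.files(out_dir, full.names = TRUE)))
}
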