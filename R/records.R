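#' Classify a carcass as dark cutting from ultimate pH
#'
#' Under Meat Standards Australia grading, a carcass with ultimate pH of 5.7
#' or above is non-compliant ("dark cutting"); the boundary value 5.7 itself
#' is non-compliant.
#'
#' @param ph_u Ultimate pH, measured in the loin 12-48 h post-mortem; must lie
#'   in the plausible range 4.5-7.5.
#' @return Logical vector: `TRUE` for dark cutting.
#' @examples
#' classify_dc(c(5.69, 5.70, 6.1)) # FALSE TRUE TRUE
#' @export
classify_dc <- function(ph_u) {
  check_numeric(ph_u, "ph_u")
  if (any(ph_u < 4.5 | ph_u > 7.5, na.rm = TRUE)) {
    stop("ultimate pH outside the plausible range [4.5, 7.5]", call. = FALSE)
  }
  ph_u >= 5.7
}

#' Read feedlot animal records
#'
#' @param path CSV path with columns `nlis,lot,feedlot,induction_date,
#'   exit_date,entry_weight,exit_weight,sex,hgp,morbidity,exit_time,
#'   arrival_time` (extra columns are carried through).
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(nlis = "animal_id")`.
#' @return Tibble of animal records with parsed dates.
#' @export
read_animals <- function(path, col_map = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  x <- apply_col_map(x, col_map)
  for (col in c("induction_date", "exit_date")) {
    if (col %in% names(x) && !inherits(x[[col]], "Date")) {
      x[[col]] <- as.Date(x[[col]])
    }
  }
  for (col in c("exit_time", "arrival_time")) {
    if (col %in% names(x) && is.character(x[[col]]) &&
        any(grepl("\\d{4}-\\d{2}-\\d{2}", x[[col]]))) {
      x[[col]] <- as.POSIXct(x[[col]], tz = "UTC")
    }
  }
  x
}

#' Read carcass grading records
#'
#' @param path CSV path with columns
#'   `nlis,abattoir,kill_date,ph_u,loin_temp,hump_height`.
#' @param col_map Optional column mapping as in [read_animals()].
#' @return Tibble of carcass records; `kill_date` parsed to `Date`.
#' @export
read_carcasses <- function(path, col_map = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  x <- apply_col_map(x, col_map)
  if ("kill_date" %in% names(x) && !inherits(x$kill_date, "Date")) {
    x$kill_date <- as.Date(x$kill_date)
  }
  x
}

#' Derive days on feed, average daily gain and transport time
#'
#' Fills the derived production covariates:
#' * `dof` — days on feed, the whole-day calendar difference exit minus
#'   induction;
#' * `adg` — average daily gain, `(exit_weight - entry_weight) / dof` in
#'   kg/day, left `NA` (and counted in the report) when `dof` is zero;
#' * `transport_hours` — arrival at the abattoir minus feedlot exit. When
#'   only clock times are available (hand-written trucking sheets record no
#'   date), a negative difference is read as an overnight haul and 24 h is
#'   added once; differences beyond 24 h are rejected as data errors.
#'
#' @param animals Animal records tibble.
#' @return The tibble with `dof`, `adg`, `transport_hours` filled and an
#'   attribute `derive_report` listing the number of `dof == 0` animals
#'   excluded from ADG.
#' @export
derive_fields <- function(animals) {
  x <- tibble::as_tibble(animals)
  if (any(x$exit_date < x$induction_date, na.rm = TRUE)) {
    bad <- x$nlis[which(x$exit_date < x$induction_date)]
    stop("exit date precedes induction date for: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  x$dof <- as.integer(x$exit_date - x$induction_date)
  zero_dof <- !is.na(x$dof) & x$dof == 0
  x$adg <- ifelse(zero_dof, NA_real_,
                  (x$exit_weight - x$entry_weight) / x$dof)
  x$transport_hours <- transport_hours(x)
  attr(x, "derive_report") <- list(n_zero_dof = sum(zero_dof))
  x
}

transport_hours <- function(x) {
  if (!all(c("exit_time", "arrival_time") %in% names(x))) {
    return(rep(NA_real_, nrow(x)))
  }
  et <- x$exit_time
  at <- x$arrival_time
  if (inherits(et, "POSIXct") && inherits(at, "POSIXct")) {
    h <- as.numeric(difftime(at, et, units = "hours"))
    if (any(h < 0, na.rm = TRUE)) {
      stop("arrival datetime precedes exit datetime", call. = FALSE)
    }
    return(h)
  }
  # clock-times only ("HH:MM"): apply the overnight rule
  to_hours <- function(s) {
    p <- strsplit(as.character(s), ":", fixed = TRUE)
    vapply(p, function(q) {
      if (length(q) < 2 || anyNA(suppressWarnings(as.numeric(q[1:2])))) {
        return(NA_real_)
      }
      as.numeric(q[1]) + as.numeric(q[2]) / 60
    }, numeric(1))
  }
  h <- to_hours(at) - to_hours(et)
  h <- ifelse(!is.na(h) & h < 0, h + 24, h)
  if (any(h > 24, na.rm = TRUE)) {
    stop("transport time exceeds 24 h; clock-time records cannot span ",
         "more than one night", call. = FALSE)
  }
  h
}

#' Merge animal and carcass records by NLIS identifier
#'
#' Inner join on the unique animal identifier, with a full account of
#' unmatched records on both sides (nothing is silently dropped). The merged
#' records gain the dark-cutting flag `dc` from [classify_dc()].
#'
#' @param animals,carcasses Tibbles keyed by `nlis`; duplicates within either
#'   input are a validation error.
#' @return A list with `records` (merged tibble, one row per matched NLIS)
#'   and `report` (`matched`, `unmatched_animals`, `unmatched_carcasses` id
#'   vectors and counts).
#' @export
merge_records <- function(animals, carcasses) {
  for (nm in c("animals", "carcasses")) {
    ids <- get(nm)$nlis
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0L) {
      stop("duplicate NLIS id(s) in ", nm, ": ",
           paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
    }
  }
  records <- dplyr::inner_join(animals, carcasses, by = "nlis")
  if ("ph_u" %in% names(records)) {
    records$dc <- classify_dc(records$ph_u)
  }
  report <- list(
    matched = nrow(records),
    unmatched_animals = setdiff(animals$nlis, carcasses$nlis),
    unmatched_carcasses = setdiff(carcasses$nlis, animals$nlis)
  )
  report$n_unmatched_animals <- length(report$unmatched_animals)
  report$n_unmatched_carcasses <- length(report$unmatched_carcasses)
  list(records = records, report = report)
}

#' Dark-cutting incidence table by group
#'
#' Tabulates total, compliant and dark-cutting carcass counts per level of a
#' grouping variable, with the percentage under either denominator
#' convention: `"total"` (dark cutters over all carcasses, the standard
#' epidemiological incidence) or `"compliant"` (dark cutters over compliant
#' carcasses, the convention some industry summaries use).
#'
#' @param records Merged records with a logical `dc` column.
#' @param by Name of the grouping column (e.g. `"feedlot"`, `"hgp"`, `"sex"`).
#' @param denominator `"total"` (default) or `"compliant"`.
#' @return Tibble with columns `group`, `total`, `compliant`, `dc`, `pct`
#'   (percentage, rounded to 2 decimals).
#' @export
incidence_table <- function(records, by, denominator = c("total", "compliant")) {
  denominator <- match.arg(denominator)
  if (!by %in% names(records)) {
    stop("grouping column `", by, "` not found", call. = FALSE)
  }
  if (nrow(records) == 0L) {
    return(tibble::tibble(group = character(0), total = integer(0),
                          compliant = integer(0), dc = integer(0),
                          pct = numeric(0)))
  }
  tab <- records |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::summarise(total = dplyr::n(), dc = sum(.data$dc), .groups = "drop") |>
    dplyr::mutate(compliant = .data$total - .data$dc)
  denom <- if (denominator == "total") tab$total else tab$compliant
  tab$pct <- round(100 * tab$dc / denom, 2)
  tab$pct[denom == 0] <- 0
  tab[, c("group", "total", "compliant", "dc", "pct")]
}

#' Crude odds ratio from a 2x2 table
#'
#' `OR = (a d) / (b c)` with a Wald 95% interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. If any single cell is
#' zero the Haldane-Anscombe correction adds 0.5 to every cell; two zero
#' cells in the same margin leave the odds ratio undefined and raise an
#' error.
#'
#' @param a,b,c,d Cell counts: `a` exposed cases, `b` exposed non-cases,
#'   `c` unexposed cases, `d` unexposed non-cases.
#' @return Tibble with `or`, `ci_low`, `ci_high`, `log_or`, `se_log`.
#' @examples
#' crude_odds_ratio(3410, 99001, 646, 37765)
#' @export
crude_odds_ratio <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0)) {
    stop("odds ratio undefined: a full margin of the 2x2 table is zero",
         call. = FALSE)
  }
  if (any(cells == 0)) cells <- cells + 0.5
  log_or <- unname(log(cells["a"]) + log(cells["d"]) -
                     log(cells["b"]) - log(cells["c"]))
  se <- sqrt(sum(1 / cells))
  tibble::tibble(
    or = exp(log_or),
    ci_low = exp(log_or - 1.96 * se),
    ci_high = exp(log_or + 1.96 * se),
    log_or = unname(log_or),
    se_log = se
  )
}

#' Annual economic loss from dark cutting
#'
#' Industry-scale cost of dark cutting: number of carcasses times mean
#' carcass weight times the per-kg price deduction applied to a dark cutter,
#' times the incidence proportion.
#'
#' @param n_carcasses Annual carcass count.
#' @param mean_cwt Mean carcass weight, kg.
#' @param deduction Price deduction for a dark cutter, currency per kg
#'   (e.g. 0.59 AUD/kg).
#' @param incidence Dark-cutting incidence as a proportion in `[0, 1]`.
#' @return Loss in the deduction's currency.
#' @examples
#' economic_loss(2988292, 330, 0.59, 0.028) # ~ AUD 16.3 million
#' @export
economic_loss <- function(n_carcasses, mean_cwt, deduction, incidence) {
  stopifnot(n_carcasses >= 0, mean_cwt >= 0, deduction >= 0,
            incidence >= 0, incidence <= 1)
  n_carcasses * mean_cwt * deduction * incidence
}

apply_col_map <- function(x, col_map) {
  if (is.null(col_map)) return(x)
  for (canonical in names(col_map)) {
    actual <- col_map[[canonical]]
    if (!actual %in% names(x)) {
      stop("mapped column `", actual, "` not present in file", call. = FALSE)
    }
    names(x)[names(x) == actual] <- canonical
  }
  x
}
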