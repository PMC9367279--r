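#' Specify a dark-cutting risk model
#'
#' Four model families are supported, mirroring the analysis design:
#'
#' * `base` — production factors only: days on feed (per 10-day increment),
#'   HGP treatment, sex, abattoir and feedlot as fixed effects, fitted as an
#'   ordinary logistic GLM. `include_morbidity = TRUE` adds the feedlot
#'   morbidity flag.
#' * `climate1` — raw weather covariates (solar radiation, wind speed, rain,
#'   relative humidity, ambient temperature).
#' * `climate2` — solar radiation, wind speed, rain and THI.
#' * `climate3` — rain and HLI summaries.
#'
#' The climatic families are mixed logistic models with sex and HGP as fixed
#' effects and feedlot and slaughter date as crossed random intercepts. Each
#' comes in variants selecting which 7-day summary enters: `"mean"`,
#' `"range"`, `"max"`, `"min"` for `climate1`/`climate2` (solar radiation and
#' wind speed stay at their daily means except in the max variant, matching
#' the tabulated model layouts), and `"mean"`, `"max"`, `"hli86"` (hours per
#' day at HLI >= 86) or `"hli_lt70"` (days with >= 6 h at HLI <= 70) for
#' `climate3`. Rain total always enters the climatic models.
#'
#' @param name One of `"base"`, `"climate1"`, `"climate2"`, `"climate3"`.
#' @param variant Variant for the climatic families; ignored for `base`.
#' @param include_morbidity Add the morbidity term to the base model
#'   (off by default, matching the reported base-model rows).
#' @return A `model_spec` list with `fixed_terms`, `random_terms` and
#'   `reference_levels`.
#' @export
model_spec <- function(name = c("base", "climate1", "climate2", "climate3"),
                       variant = NULL, include_morbidity = FALSE) {
  name <- match.arg(name)
  refs <- list(hgp = "no", sex = "F", feedlot = "A", abattoir = "A",
               morbidity = "no")
  if (name == "base") {
    fixed <- c("dof10", "hgp", "sex", "abattoir", "feedlot")
    if (include_morbidity) fixed <- c(fixed, "morbidity")
    return(structure(list(name = name, variant = NULL, fixed_terms = fixed,
                          random_terms = character(0),
                          reference_levels = refs),
                     class = "model_spec"))
  }
  variant <- variant %||% "mean"
  fixed <- c("sex", "hgp", climate_terms(name, variant))
  structure(list(name = name, variant = variant, fixed_terms = fixed,
                 random_terms = c("feedlot", "slaughter_date"),
                 reference_levels = refs),
            class = "model_spec")
}

climate_terms <- function(name, variant) {
  if (name == "climate1") {
    sets <- list(
      mean  = c("sr_mean", "ws_mean", "rh_mean", "ta_mean"),
      range = c("sr_mean", "ws_mean", "rh_range", "ta_range"),
      max   = c("sr_max", "ws_max", "rh_max", "ta_max"),
      min   = c("sr_mean", "ws_min", "rh_min", "ta_min")
    )
  } else if (name == "climate2") {
    sets <- list(
      mean  = c("sr_mean", "ws_mean", "thi_mean"),
      range = c("sr_mean", "ws_mean", "thi_range"),
      max   = c("sr_max", "ws_max", "thi_max"),
      min   = c("sr_mean", "ws_min", "thi_min")
    )
  } else {
    sets <- list(
      mean     = "hli_mean",
      max      = "hli_max",
      hli86    = "hours_hli_ge86_per_day",
      hli_lt70 = "days_hli_le70_ge6h"
    )
  }
  if (!variant %in% names(sets)) {
    stop("unknown variant `", variant, "` for ", name, "; expected one of: ",
         paste(names(sets), collapse = ", "), call. = FALSE)
  }
  c(sets[[variant]], "rain_total_7")
}

#' Build the outcome, design matrix and grouping factors for a model
#'
#' Expands categorical factors against fixed reference levels (feedlot A,
#' abattoir A, HGP no, sex F), scales days on feed to 10-day increments, and
#' drops records with missing covariates (counted, never silent). Aliased
#' (linearly dependent) columns are detected by QR and removed with a record
#' of their names: with some consignment structures a feedlot indicator is
#' fully determined by the abattoir indicators and cannot be separately
#' estimated.
#'
#' @param records Merged analysis records with `dc` and the covariates the
#'   spec names (exposure columns for climatic specs).
#' @param spec A [model_spec()].
#' @return List with `y` (0/1 outcome), `X` (design matrix), `groups` (named
#'   list of factors for random intercepts; empty for the base model),
#'   `n_dropped`, and `aliased` (names of removed columns).
#' @export
build_design <- function(records, spec) {
  df <- tibble::as_tibble(records)
  if (!"dc" %in% names(df)) stop("records lack the `dc` outcome", call. = FALSE)

  need <- spec$fixed_terms
  if ("dof10" %in% need) {
    if (!"dof" %in% names(df)) stop("records lack `dof`", call. = FALSE)
    df$dof10 <- df$dof / 10
  }
  if (length(spec$random_terms) > 0 && "exposure_missing" %in% names(df)) {
    df <- df[!df$exposure_missing, , drop = FALSE]
  }
  missing_need <- setdiff(need, names(df))
  if (length(missing_need) > 0L) {
    stop("records lack covariate(s): ", paste(missing_need, collapse = ", "),
         call. = FALSE)
  }
  group_cols <- c(feedlot = "feedlot", slaughter_date = "kill_date")
  used_groups <- group_cols[spec$random_terms]

  keep_cols <- c("dc", need, unname(used_groups))
  complete <- stats::complete.cases(df[, keep_cols, drop = FALSE])
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  if (nrow(df) == 0L) stop("no complete records to fit", call. = FALSE)

  for (fct in intersect(c("hgp", "sex", "abattoir", "feedlot", "morbidity"), need)) {
    ref <- spec$reference_levels[[fct]]
    lv <- sort(unique(as.character(df[[fct]])))
    if (length(lv) < 2L) {
      stop("factor `", fct, "` has a single level; cannot be estimated",
           call. = FALSE)
    }
    df[[fct]] <- factor(df[[fct]], levels = union(intersect(ref, lv), lv))
  }

  form <- stats::as.formula(paste("~", paste(need, collapse = " + ")))
  X <- stats::model.matrix(form, data = df)

  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    X <- X[, sort(keep), drop = FALSE]
  }

  groups <- list()
  for (g in spec$random_terms) {
    groups[[g]] <- factor(as.character(df[[group_cols[[g]]]]))
  }

  list(y = as.integer(df$dc), X = X, groups = groups,
       n_dropped = n_dropped, aliased = aliased)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit (via `stats::glm.fit`, convergence
#' tolerance 1e-8 on the deviance) returning a coefficient table with Wald
#' standard errors from the inverse observed information, odds ratios and
#' 95% intervals. Coefficients whose standardised magnitude exceeds 15
#' suggest complete separation and set a warning flag on the result rather
#' than failing.
#'
#' @param y 0/1 outcome vector.
#' @param X Design matrix (include the intercept column explicitly); must be
#'   full rank.
#' @return A `darkcut_fit` object; see [model_spec()] for the model families.
#' @export
fit_logistic <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100))
  beta <- fit$coefficients
  w <- fit$weights
  vc <- solve(crossprod(X * sqrt(w)))
  se <- sqrt(diag(vc))
  ll <- sum(stats::dbinom(y, 1, fit$fitted.values, log = TRUE))

  flags <- character(0)
  sds <- apply(X, 2, stats::sd)
  scaled <- abs(beta) * ifelse(sds > 0, sds, 1)
  if (any(scaled[sds > 0] > 15)) {
    flags <- c(flags, paste0(
      "possible separation in: ",
      paste(colnames(X)[sds > 0 & scaled > 15], collapse = ", ")))
  }

  new_fit_result(
    terms = colnames(X), estimate = beta, se = se,
    ranef_var = NULL, loglik = ll, n = length(y),
    converged = isTRUE(fit$converged), flags = flags
  )
}

#' Fit a mixed logistic regression with random intercepts
#'
#' Random-intercept logistic model estimated by Laplace-approximate maximum
#' likelihood through [lme4::glmer()]. Grouping factors are treated as
#' crossed, independent random intercepts. When every estimated
#' random-effect variance is (numerically) zero the fixed effects coincide
#' with the plain logistic fit.
#'
#' @param y 0/1 outcome vector.
#' @param X Design matrix including the intercept column.
#' @param groups Named list of factors, each with at least 2 levels.
#' @return A `darkcut_fit` object with `ranef_var` filled.
#' @export
fit_mixed_logistic <- function(y, X, groups) {
  X <- as.matrix(X)
  if (length(groups) == 0L) stop("no grouping factors supplied", call. = FALSE)
  for (g in names(groups)) {
    if (nlevels(droplevels(factor(groups[[g]]))) < 2L) {
      stop("grouping factor `", g, "` has fewer than 2 levels", call. = FALSE)
    }
  }
  pretty <- colnames(X)
  safe <- make.names(pretty, unique = TRUE)
  df <- as.data.frame(X)
  names(df) <- safe
  df$.y <- y
  for (g in names(groups)) df[[paste0(".g_", g)]] <- droplevels(factor(groups[[g]]))

  rhs <- paste(c(safe, sprintf("(1 | .g_%s)", names(groups))), collapse = " + ")
  form <- stats::as.formula(paste(".y ~ 0 +", rhs))

  warn <- character(0)
  m <- withCallingHandlers(
    lme4::glmer(form, data = df, family = stats::binomial(),
                control = lme4::glmerControl(
                  calc.derivs = FALSE,
                  check.conv.singular = "ignore")),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  beta <- lme4::fixef(m)
  names(beta) <- pretty[match(names(beta), safe)]
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  vc_df <- as.data.frame(lme4::VarCorr(m))
  ranef_var <- stats::setNames(vc_df$vcov,
                               sub("^\\.g_", "", vc_df$grp))
  conv_ok <- length(m@optinfo$conv$lme4) == 0 &&
    (is.null(m@optinfo$conv$opt) || m@optinfo$conv$opt == 0)

  new_fit_result(
    terms = names(beta), estimate = unname(beta), se = unname(se),
    ranef_var = ranef_var, loglik = as.numeric(stats::logLik(m)),
    n = length(y), converged = conv_ok, flags = warn
  )
}

new_fit_result <- function(terms, estimate, se, ranef_var, loglik, n,
                           converged, flags = character(0),
                           model = NULL, variant = NULL,
                           n_dropped = 0L, aliased = character(0)) {
  terms <- unname(terms)
  estimate <- unname(estimate)
  se <- unname(se)
  z <- estimate / se
  structure(
    list(
      model = model, variant = variant,
      coefficients = tibble::tibble(
        term = unname(terms),
        estimate = unname(estimate),
        se = unname(se),
        or = exp(estimate),
        ci_low = exp(estimate - 1.96 * se),
        ci_high = exp(estimate + 1.96 * se),
        p = 2 * stats::pnorm(-abs(z))
      ),
      ranef_var = ranef_var,
      loglik = loglik,
      n = n,
      converged = converged,
      flags = flags,
      n_dropped = n_dropped,
      aliased = aliased
    ),
    class = "darkcut_fit"
  )
}

#' @method print darkcut_fit
#' @export
print.darkcut_fit <- function(x, ...) {
  hdr <- if (is.null(x$model)) "logistic fit" else {
    paste0(x$model, if (!is.null(x$variant)) paste0(" (", x$variant, ")"))
  }
  cat("<darkcut_fit> ", hdr, ": n = ", x$n,
      ", logLik = ", formatC(x$loglik, format = "f", digits = 1),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  if (!is.null(x$ranef_var) && length(x$ranef_var) > 0) {
    cat("random-effect variances:\n")
    print(round(x$ranef_var, 5))
  }
  if (length(x$flags) > 0) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Coefficient table of a fit
#'
#' @param fit A `darkcut_fit`.
#' @return Tibble `term, estimate, se, or, ci_low, ci_high, p`.
#' @export
coef_table <- function(fit) fit$coefficients

#' Default model suite: the base model and twelve climatic variants
#'
#' @param include_morbidity Passed to the base [model_spec()].
#' @return Named list of 13 `model_spec`s.
#' @export
default_model_specs <- function(include_morbidity = FALSE) {
  specs <- list(base = model_spec("base", include_morbidity = include_morbidity))
  for (v in c("mean", "range", "max", "min")) {
    specs[[paste0("climate1_", v)]] <- model_spec("climate1", v)
    specs[[paste0("climate2_", v)]] <- model_spec("climate2", v)
  }
  for (v in c("mean", "max", "hli86", "hli_lt70")) {
    specs[[paste0("climate3_", v)]] <- model_spec("climate3", v)
  }
  specs
}

#' Fit the full model suite
#'
#' Runs the base logistic model and the twelve climatic mixed-model variants
#' on merged, exposure-attached records. Per-fit failures (for instance, no
#' records with climate exposure) become skip notices rather than aborting
#' the suite.
#'
#' @param records Merged analysis records (with exposure columns for the
#'   climatic fits).
#' @param specs List of [model_spec()]s; defaults to [default_model_specs()].
#' @return A `darkcut_suite`: list with `fits` (named `darkcut_fit`s) and
#'   `notices` (named character vector of skip reasons).
#' @export
run_model_suite <- function(records, specs = default_model_specs()) {
  fits <- list()
  notices <- character(0)
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    res <- tryCatch({
      d <- build_design(records, spec)
      fit <- if (length(d$groups) > 0) {
        fit_mixed_logistic(d$y, d$X, d$groups)
      } else {
        fit_logistic(d$y, d$X)
      }
      fit$model <- spec$name
      fit$variant <- spec$variant
      fit$n_dropped <- d$n_dropped
      fit$aliased <- d$aliased
      fit
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      notices[nm] <- res
    } else {
      fits[[nm]] <- res
    }
  }
  structure(list(fits = fits, notices = notices), class = "darkcut_suite")
}

#' @method print darkcut_suite
#' @export
print.darkcut_suite <- function(x, ...) {
  cat("<darkcut_suite> ", length(x$fits), " fit(s), ",
      length(x$notices), " skip notice(s)\n", sep = "")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat("  ", nm, ": n = ", f$n,
        if (!f$converged) " [NOT CONVERGED]", "\n", sep = "")
  }
  for (nm in names(x$notices)) {
    cat("  ", nm, " [skipped]: ", x$notices[[nm]], "\n", sep = "")
  }
  invisible(x)
}
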