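test_that("design construction scales DOF, expands references, and drops aliased columns", {
  st <- make_small_study(n_total = 1500, seed = 12)
  d <- build_design(st$records, model_spec("base"))
  expect_true(all(c("(Intercept)", "dof10", "hgpyes", "sexM",
                    "abattoirB", "abattoirC", "feedlotB") %in% colnames(d$X)))
  # DOF enters per 10-day increment
  expect_equal(d$n_dropped, 0)
  expect_equal(unname(d$X[, "dof10"]), st$records$dof / 10)
  # feedlots D and E consign only to abattoir A, so one indicator is aliased
  expect_equal(d$aliased, "feedlotE")
  expect_equal(qr(d$X)$rank, ncol(d$X))

  one_level <- st$records
  one_level$sex <- "M"
  expect_error(build_design(one_level, model_spec("base")), "sex")

  # climatic specs need the exposure covariates
  expect_error(build_design(st$records, model_spec("climate1", "mean")),
               "sr_mean")
})

test_that("logistic fit matches closed forms: intercept-only and saturated 2x2", {
  set.seed(21)
  n <- 4000
  y <- rbinom(n, 1, 0.23)
  f0 <- fit_logistic(y, matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  p <- mean(y)
  expect_equal(f0$coefficients$estimate, log(p / (1 - p)), tolerance = 1e-8)

  x <- rbinom(n, 1, 0.5)
  y <- as.integer(runif(n) < plogis(-2 + 0.9 * x))
  X <- cbind("(Intercept)" = 1, x = x)
  f1 <- fit_logistic(y, X)
  a <- sum(y & x); b <- sum(!y & x); c <- sum(y & !x); d <- sum(!y & !x)
  oracle <- crude_odds_ratio(a, b, c, d)
  expect_equal(f1$coefficients$or[2], oracle$or, tolerance = 1e-6)
  expect_equal(f1$coefficients$se[2], oracle$se_log, tolerance = 1e-6)

  # null 2x2: fitted OR near 1
  y0 <- rbinom(n, 1, 0.3)
  f2 <- fit_logistic(y0, X)
  expect_lt(abs(f2$coefficients$estimate[2]), 3 * f2$coefficients$se[2])

  expect_error(fit_logistic(y, cbind(X, x2 = x)), "aliased")
})

test_that("logistic likelihood ascends and coefficients rescale with their covariates", {
  set.seed(31)
  n <- 3000
  z <- rnorm(n, 10, 3)
  y <- as.integer(runif(n) < plogis(-1 + 0.15 * z))
  X <- cbind("(Intercept)" = 1, z = z)
  fit <- fit_logistic(y, X)
  f0 <- fit_logistic(y, X[, 1, drop = FALSE])
  expect_gte(fit$loglik, f0$loglik)

  k <- 10
  Xk <- cbind("(Intercept)" = 1, zk = z * k)
  fitk <- fit_logistic(y, Xk)
  expect_equal(fitk$coefficients$estimate[2], fit$coefficients$estimate[2] / k,
               tolerance = 1e-6)
  # per-original-unit OR unchanged
  expect_equal(exp(fitk$coefficients$estimate[2] * k),
               fit$coefficients$or[2], tolerance = 1e-6)
})

test_that("separation sets a warning flag instead of failing", {
  y <- c(rep(0, 30), rep(1, 30))
  X <- cbind("(Intercept)" = 1, x = y)  # perfect separation
  fit <- suppressWarnings(fit_logistic(y, X))
  expect_true(any(grepl("separation", fit$flags)))
})

test_that("mixed fits with zero group variance reduce to the plain logistic fit", {
  agree <- 0L; degenerate_seen <- FALSE
  for (s in c(1, 4, 6)) {
    set.seed(s)
    n <- 4000
    g1 <- factor(sample(LETTERS[1:6], n, TRUE))
    g2 <- factor(sample(1:30, n, TRUE))
    x <- rbinom(n, 1, 0.5)
    y <- as.integer(runif(n) < plogis(-2 + 0.8 * x))
    X <- cbind("(Intercept)" = 1, x = x)
    glm_fit <- fit_logistic(y, X)
    glmm_fit <- fit_mixed_logistic(y, X, list(feedlot = g1, slaughter_date = g2))
    expect_equal(sort(names(glmm_fit$ranef_var)),
                 c("feedlot", "slaughter_date"))
    if (all(glmm_fit$ranef_var < 1e-8)) {
      degenerate_seen <- TRUE
      expect_equal(glmm_fit$coefficients$estimate, glm_fit$coefficients$estimate,
                   tolerance = 1e-4)
    }
  }
  expect_true(degenerate_seen)

  expect_error(
    fit_mixed_logistic(rbinom(50, 1, 0.3), matrix(1, 50, 1),
                       list(g = factor(rep("only", 50)))),
    "fewer than 2 levels")
})

test_that("mixed fit recovers a known random-intercept variance", {
  set.seed(11)
  n_g <- 200; n_per <- 200
  g <- factor(rep(seq_len(n_g), each = n_per))
  u <- rnorm(n_g, 0, 0.5)  # variance 0.25
  y <- as.integer(runif(n_g * n_per) < plogis(-2 + u[as.integer(g)]))
  fit <- fit_mixed_logistic(y, matrix(1, n_g * n_per, 1,
                                      dimnames = list(NULL, "(Intercept)")),
                            list(g = g))
  # sampling sd of a variance estimate over 200 groups is about 0.025
  expect_equal(unname(fit$ranef_var["g"]), 0.25, tolerance = 0.4)
  expect_true(abs(fit$ranef_var["g"] - 0.25) < 0.1)
})

test_that("the model suite runs 13 fits with exposures and skips the climatic ones without", {
  st <- make_small_study(n_total = 1200, seed = 33)
  suite <- run_model_suite(st$records)
  expect_equal(length(suite$fits) + length(suite$notices), 13)
  expect_true("base" %in% names(suite$fits))
  expect_equal(length(suite$notices), 12)  # no exposure columns present
  expect_true(all(grepl("climate", names(suite$notices))))

  # base coefficient rows come in the documented order
  ct <- coef_table(suite$fits$base)
  expect_equal(ct$term[1:4], c("(Intercept)", "dof10", "hgpyes", "sexM"))
  expect_true(all(ct$ci_low <= ct$or & ct$or <= ct$ci_high))
  expect_equal(ct$or, exp(ct$estimate), tolerance = 1e-12)
})
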