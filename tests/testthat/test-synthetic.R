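test_that("weather generation is deterministic under a seed and physically plausible", {
  cfg <- weather_sim_config(n_days = 20, seed = 8)
  w1 <- simulate_weather(cfg)
  w2 <- simulate_weather(cfg)
  expect_identical(w1, w2)
  expect_equal(nrow(w1), 20 * 96)

  # generated series pass QC with nothing masked
  qc <- qc_and_resample(w1)
  expect_equal(sum(qc$report$masked), 0)
  expect_equal(sum(qc$report$missing_after), 0)

  # solar radiation is zero at local midnight
  midnight <- format(w1$timestamp, "%H:%M") == "00:00"
  expect_true(all(w1$sr[midnight] == 0))

  # no diurnal cycle and no noise: flat within-day temperature
  flat <- simulate_weather(weather_sim_config(n_days = 5, seed = 9,
                                              ta_diurnal_amplitude = 0,
                                              ta_noise_sd = 0))
  day <- as.Date(flat$timestamp, tz = "UTC")
  ranges <- tapply(flat$ta, day, function(x) diff(range(x)))
  expect_true(all(ranges < 0.3))  # only the slow seasonal drift remains

  # byte-identical CSV under the same seed
  dir <- withr::local_tempdir()
  readr::write_csv(w1, file.path(dir, "a.csv"))
  readr::write_csv(simulate_weather(cfg), file.path(dir, "b.csv"))
  expect_identical(readBin(file.path(dir, "a.csv"), "raw", 1e7),
                   readBin(file.path(dir, "b.csv"), "raw", 1e7))
})

test_that("herd generation hits the configured marginal compositions", {
  cfg <- herd_sim_config(n_total = 30000, seed = 14)
  sim <- simulate_herd(cfg)
  expect_identical(sim$animals, simulate_herd(cfg)$animals)
  expect_equal(nrow(sim$animals), sum(cfg$feedlots$n_animals))

  # realised HGP fraction tracks the configured mixture within binomial noise
  target_hgp <- with(cfg$feedlots, sum(n_animals * hgp_prob) / sum(n_animals))
  expect_equal(mean(sim$animals$hgp == "yes"), target_hgp, tolerance = 0.01)
  target_male <- with(cfg$feedlots, sum(n_animals * male_prob) / sum(n_animals))
  expect_equal(mean(sim$animals$sex == "M"), target_male, tolerance = 0.01)

  # feedlot with zero animals vanishes downstream
  fl <- cfg$feedlots; fl$n_animals[fl$feedlot == "E"] <- 0L
  sim0 <- simulate_herd(herd_sim_config(feedlots = fl, seed = 14))
  expect_false("E" %in% sim0$animals$feedlot)

  # hump heights are non-negative multiples of 5 mm
  expect_true(all(sim$carcass_base$hump_height %% 5 == 0))
  expect_true(all(sim$carcass_base$hump_height >= 0))
})

test_that("outcome generation is consistent with its own logistic model", {
  # null effects at intercept log(0.03/0.97): incidence near 3%
  fl <- default_feedlots()
  cfg0 <- herd_sim_config(
    feedlots = fl, n_total = 100000,
    true_coefficients = c(`(Intercept)` = log(0.03 / 0.97)),
    seed = 15
  )
  sim <- simulate_herd(cfg0)
  rec <- dplyr::inner_join(derive_fields(sim$animals), sim$carcass_base,
                           by = "nlis")
  out <- simulate_outcomes(rec, NULL, cfg0)
  expect_equal(mean(out$dc), 0.03, tolerance = 3 * sqrt(0.03 * 0.97 / nrow(out)) / 0.03)

  # the pH draw reproduces the simulated flag exactly
  expect_identical(classify_dc(out$ph_u), out$dc)
  expect_true(all(out$ph_u >= 4.5 & out$ph_u <= 7.5))

  # a single HGP effect converges to its generating log-odds (3 MC SEs)
  fl2 <- fl; fl2$hgp_prob <- 0.5
  cfg1 <- herd_sim_config(
    feedlots = fl2, n_total = 100000,
    true_coefficients = c(`(Intercept)` = log(0.05), hgpyes = log(2.29)),
    seed = 16
  )
  sim1 <- simulate_herd(cfg1)
  rec1 <- dplyr::inner_join(derive_fields(sim1$animals), sim1$carcass_base,
                            by = "nlis")
  out1 <- simulate_outcomes(rec1, NULL, cfg1)
  hgp <- rec1$hgp == "yes"
  a <- sum(out1$dc & hgp); b <- sum(!out1$dc & hgp)
  c_ <- sum(out1$dc & !hgp); d <- sum(!out1$dc & !hgp)
  o <- crude_odds_ratio(a, b, c_, d)
  expect_lt(abs(o$log_or - log(2.29)), 3 * o$se_log)

  expect_error(
    simulate_outcomes(rec1, tibble::tibble(nlis = rec1$nlis,
                                           exposure_missing = FALSE),
                      herd_sim_config(true_coefficients = c(banana = 1))),
    "no matching covariate")
})

test_that("nonzero random intercepts shift outcomes between slaughter dates", {
  cfg <- herd_sim_config(n_total = 20000, random_sd_date = 1.5,
                         true_coefficients = c(`(Intercept)` = log(0.05)),
                         seed = 44)
  sim <- simulate_herd(cfg)
  rec <- dplyr::inner_join(derive_fields(sim$animals), sim$carcass_base,
                           by = "nlis")
  out <- simulate_outcomes(rec, NULL, cfg)
  eta_by_date <- tapply(out$eta, as.character(out$kill_date), mean)
  expect_gt(stats::sd(eta_by_date), 0.5)

  cfg0 <- cfg; cfg0$random_sd_date <- 0
  sim0 <- simulate_herd(cfg0)
  rec0 <- dplyr::inner_join(derive_fields(sim0$animals), sim0$carcass_base,
                            by = "nlis")
  out0 <- simulate_outcomes(rec0, NULL, cfg0)
  expect_equal(stats::sd(tapply(out0$eta, as.character(out0$kill_date), mean)), 0)
})

test_that("the recovery harness reports one row per estimated term", {
  rep1 <- recovery_report(1, herd_sim_config(n_total = 6000),
                          model_spec("base"), seed = 5)
  expect_true(all(c("term", "true_or", "mean_or", "coverage") %in% names(rep1)))
  expect_true(all(rep1$n_replicates == 1))
  expect_true(all(rep1$coverage %in% c(0, 1)))
  # every reported term has a generating value
  expect_true(all(rep1$term %in% names(default_true_coefficients())))
})
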