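test_that("dark-cutting classification is boundary-inclusive at pH 5.7", {
  expect_true(classify_dc(5.70))
  expect_false(classify_dc(5.69))
  expect_true(classify_dc(6.10))
  expect_equal(classify_dc(c(5.5, 5.7, 7.0)), c(FALSE, TRUE, TRUE))
  expect_error(classify_dc(8.2), "plausible")
  expect_error(classify_dc(3.9), "plausible")
})

test_that("derived production fields follow their definitions", {
  animals <- tibble::tibble(
    nlis = c("N1", "N2"),
    induction_date = as.Date(c("2017-10-01", "2017-12-01")),
    exit_date = as.Date(c("2018-01-09", "2017-12-01")),
    entry_weight = c(380, 400), exit_weight = c(680, 400),
    exit_time = c("22:00", "08:00"), arrival_time = c("03:00", "10:30")
  )
  out <- derive_fields(animals)
  expect_equal(out$dof, c(100L, 0L))
  expect_equal(out$adg[1], 3.0)
  expect_true(is.na(out$adg[2]))  # dof == 0 excluded from ADG
  expect_equal(attr(out, "derive_report")$n_zero_dof, 1L)
  # clock-time-only transport applies the overnight rule once
  expect_equal(out$transport_hours, c(5, 2.5))

  bad <- animals; bad$exit_date[1] <- as.Date("2017-09-01")
  expect_error(derive_fields(bad), "precedes")
})

test_that("merging is an inner join with a full account of unmatched ids", {
  animals <- tibble::tibble(nlis = c("N1", "N2", "N3"),
                            feedlot = "A",
                            induction_date = as.Date("2017-10-01"),
                            exit_date = as.Date("2018-01-09"))
  carcasses <- tibble::tibble(nlis = c("N2", "N3", "N4"),
                              ph_u = c(5.5, 5.9, 5.6))
  m <- merge_records(animals, carcasses)
  expect_equal(m$report$matched, 2)
  expect_equal(m$report$unmatched_animals, "N1")
  expect_equal(m$report$unmatched_carcasses, "N4")
  expect_equal(m$records$dc, c(FALSE, TRUE))
  # conservation: matched + unmatched = input sizes
  expect_equal(m$report$matched + m$report$n_unmatched_animals, nrow(animals))
  expect_equal(m$report$matched + m$report$n_unmatched_carcasses, nrow(carcasses))

  # disjoint ids: nothing matches and everything is reported
  disjoint <- merge_records(animals, carcasses[3, ])
  expect_equal(disjoint$report$matched, 0)
  expect_equal(disjoint$report$n_unmatched_animals, 3)
  expect_equal(disjoint$report$unmatched_carcasses, "N4")
  dup <- carcasses; dup$nlis[2] <- "N2"
  expect_error(merge_records(animals, dup), "N2")
})

test_that("incidence tables partition the counts and support both denominators", {
  hgp <- expand_counts(c("yes", "no"), c(99001L, 37765L), c(3410L, 646L))
  names(hgp)[1] <- "hgp"
  tab_total <- incidence_table(hgp, "hgp", denominator = "total")
  expect_equal(tab_total$pct[tab_total$group == "yes"], 3.33)
  expect_equal(tab_total$pct[tab_total$group == "no"], 1.68)
  expect_true(all(tab_total$compliant + tab_total$dc == tab_total$total))

  fl <- study_feedlot_counts()
  rec <- expand_counts(fl$feedlot, fl$compliant, fl$dc)
  names(rec)[1] <- "feedlot"
  tab_comp <- incidence_table(rec, "feedlot", denominator = "compliant")
  expect_equal(tab_comp$pct[tab_comp$group == "G"], 5.61)
  expect_true(all(tab_comp$compliant + tab_comp$dc == tab_comp$total))

  none <- tibble::tibble(feedlot = "Z", dc = FALSE)
  expect_equal(incidence_table(none, "feedlot")$pct, 0)
  empty <- incidence_table(none[0, ], "feedlot")
  expect_equal(nrow(empty), 0)
})

test_that("crude odds ratio matches direct arithmetic and the odds-of-proportions oracle", {
  expect_equal(crude_odds_ratio(3410, 99001, 646, 37765)$or, 2.014,
               tolerance = 5e-4)
  expect_equal(crude_odds_ratio(10, 10, 10, 10)$or, 1.0)
  # Haldane-Anscombe: single zero cell gets +0.5 everywhere
  expect_equal(crude_odds_ratio(1, 1, 0, 1)$or, (1.5 * 1.5) / (1.5 * 0.5))
  expect_error(crude_odds_ratio(0, 0, 3, 4), "margin")

  # oracle: ratio of the two row-wise odds
  set.seed(5)
  for (i in 1:20) {
    cells <- rpois(4, 40) + 1
    odds1 <- (cells[1] / (cells[1] + cells[2])) / (cells[2] / (cells[1] + cells[2]))
    odds2 <- (cells[3] / (cells[3] + cells[4])) / (cells[4] / (cells[3] + cells[4]))
    expect_equal(crude_odds_ratio(cells[1], cells[2], cells[3], cells[4])$or,
                 odds1 / odds2, tolerance = 1e-10)
  }
})

test_that("economic loss is the product of scale, weight, deduction and incidence", {
  expect_equal(economic_loss(2988292, 330, 0.59, 0.028), 16290966, tolerance = 1)
  expect_equal(economic_loss(2988292, 330, 0.59, 0), 0)
  expect_equal(economic_loss(2988292, 330, 0.59, 0.056),
               2 * economic_loss(2988292, 330, 0.59, 0.028))
})

test_that("record CSV round trips preserve values and honour column mappings", {
  dir <- withr::local_tempdir()
  animals <- tibble::tibble(
    nlis = c("N1", "N2"), lot = "L1", feedlot = "A",
    induction_date = as.Date("2017-10-01"), exit_date = as.Date("2018-01-09"),
    entry_weight = c(380, 390), exit_weight = c(680, 700),
    sex = c("F", "M"), hgp = c("no", "yes"), morbidity = "no",
    exit_time = "07:00", arrival_time = "12:00"
  )
  readr::write_csv(animals, file.path(dir, "animals.csv"))
  back <- read_animals(file.path(dir, "animals.csv"))
  expect_equal(back$exit_date, animals$exit_date)
  expect_equal(back$entry_weight, animals$entry_weight)

  carc <- tibble::tibble(id = c("N1", "N2"), abattoir = "A",
                         kill_date = as.Date("2018-01-10"),
                         ph_u = c(5.5, 5.8), loin_temp = 6, hump_height = 65)
  readr::write_csv(carc, file.path(dir, "carcasses.csv"))
  mapped <- read_carcasses(file.path(dir, "carcasses.csv"),
                           col_map = c(nlis = "id"))
  expect_true("nlis" %in% names(mapped))
  expect_error(read_carcasses(file.path(dir, "carcasses.csv"),
                              col_map = c(nlis = "nope")), "not present")
})
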