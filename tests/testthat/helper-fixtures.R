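# Shared fixture builders; everything is generated in code.

make_obs <- function(n, ta = 20, rh = 50, sr = 0, ws = 1, rain = 0,
                     start = "2018-01-01 00:00:00", interval_min = 15) {
  tibble::tibble(
    timestamp = as.POSIXct(start, tz = "UTC") + interval_min * 60 * (seq_len(n) - 1),
    ta = rep_len(ta, n), rh = rep_len(rh, n), sr = rep_len(sr, n),
    ws = rep_len(ws, n), rain = rep_len(rain, n)
  )
}

# step-by-step trace of the heat-load balance rule, written directly from
# the update rule: gain (h-upper)/M above, lose (lower-h)/M below, clamp at 0
ahl_trace_oracle <- function(h, lower = 77, upper = 86, m = 4) {
  balance <- 0
  vapply(h, function(hi) {
    inc <- 0
    if (hi > upper) inc <- (hi - upper) / m
    if (hi < lower) inc <- -(lower - hi) / m
    balance <<- max(0, balance + inc)
    balance
  }, numeric(1))
}

# expand printed group counts into per-carcass records
expand_counts <- function(group, compliant, dc) {
  tibble::tibble(
    group = rep(group, times = compliant + dc),
    dc = unlist(mapply(function(cn, dn) c(rep(FALSE, cn), rep(TRUE, dn)),
                       compliant, dc, SIMPLIFY = FALSE))
  )
}

# printed feedlot-level compliant/non-compliant carcass counts (study year)
study_feedlot_counts <- function() {
  tibble::tibble(
    feedlot = LETTERS[1:7],
    total = c(18546L, 7472L, 18989L, 62349L, 6082L, 8237L, 19147L),
    compliant = c(18314L, 7236L, 18510L, 60462L, 6012L, 8102L, 18130L),
    dc = c(232L, 236L, 479L, 1887L, 70L, 135L, 1017L)
  )
}

# small synthetic herd + outcomes, via the real generator path
make_small_study <- function(n_total = 2000, seed = 99, ...) {
  cfg <- herd_sim_config(n_total = n_total, seed = seed, ...)
  sim <- simulate_herd(cfg)
  animals <- derive_fields(sim$animals)
  records <- dplyr::inner_join(animals, sim$carcass_base, by = "nlis")
  carcasses <- simulate_outcomes(records, NULL, cfg)
  merged <- merge_records(
    animals,
    carcasses[, c("nlis", "abattoir", "kill_date", "ph_u", "loin_temp",
                  "hump_height")]
  )$records
  list(cfg = cfg, animals = animals, carcasses = carcasses, records = merged)
}
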