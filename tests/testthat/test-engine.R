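test_that("one step from baseline conserves water and loses the right amount", {
  p <- hh_params()
  s <- init_state(p)
  res <- hh_step(s, p, u = 1)  # u = 1: no unregulated bout can start
  row <- res$row
  total0 <- s$ecf_v + s$icf_v
  total1 <- res$state$ecf_v + res$state$icf_v +
    res$state$stomach_v + res$state$intestine_v
  expect_equal(total1 - total0,
               row["intake_ml"] - row["urine_flow"] +
                 p$unregulated_balance_flux,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(res$state$t_min, 1L)
})

test_that("water and sodium ledgers close at every minute of a run", {
  p <- hh_params()
  s <- simulate_hh(p, days = 2, seed = 7)
  err <- ledger_errors(s, p)
  expect_lt(err$water, 1e-9)
  expect_lt(err$sodium, 1e-12)
  # cumulative columns are non-decreasing and the row count is exact
  expect_equal(nrow(s), 2 * 1440)
  expect_true(all(diff(s$cum_urine) >= 0))
  expect_true(all(diff(s$cum_intake) >= 0))
  expect_true(all(diff(s$cum_na_intake) >= 0))
})

test_that("ledgers also close under every challenge protocol", {
  p <- hh_params()
  for (prot in list(saline_challenge(days = 2),
                    furosemide_challenge(days = 2),
                    icf_block_protocol(days = 2),
                    forced_drink_protocol(days = 2))) {
    s <- simulate_hh(p, prot, seed = 3)
    err <- ledger_errors(s, p)
    expect_lt(err$water, 1e-9)
    expect_lt(err$sodium, 1e-12)
  }
})

test_that("runs are deterministic given the seed", {
  p <- hh_params()
  a <- simulate_hh(p, days = 2, seed = 17)
  b <- simulate_hh(p, days = 2, seed = 17)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("with drinking disabled the sodium concentration drifts up", {
  # degenerate configuration: no unregulated supply, unreachable threshold
  p <- hh_params(drink_threshold_frac = 1,
                 drinking = list(bout_volume_ml = 1,
                                 ingestion_rate_ml_min = 1,
                                 unregulated_na_conc = 50, p_base = 0,
                                 p_amplitude = 0, p_max_min = 120))
  s <- simulate_hh(p, days = 1, seed = 1)
  expect_equal(sum(s$intake_ml), 0)
  expect_true(all(diff(s$na_conc) > -1e-9))
  expect_gt(s$na_conc[1440], 142)
})

test_that("circadian profile averages minute-of-day across days", {
  p <- hh_params()
  s <- simulate_hh(p, days = 3, seed = 2)
  prof <- circadian_profile(s)
  expect_equal(nrow(prof), 1440)
  expect_equal(attr(prof, "days"), 3)
  # the profile mean over minutes equals the overall series mean
  expect_equal(mean(prof$na_conc_mean), mean(s$na_conc), tolerance = 1e-12)
  # a constant column has zero spread everywhere
  s$icf_blocked <- 0
  prof2 <- circadian_profile(s, vars = "icf_blocked")
  expect_true(all(prof2$icf_blocked_sd == 0))
  expect_error(circadian_profile(s[1:1440, ]), "at least 2")
})

test_that("phase detection finds the peak and the first threshold crossing", {
  # constructed two-day series with a known sawtooth AVP profile
  tod <- rep(0:1439, 2)
  peak_tod <- 1150
  avp_prof <- 2 + 3 * pmax(0, 1 - abs(0:1439 - peak_tod) / 400)
  fake <- data.frame(t_min = 0:2879, tod = tod, avp = rep(avp_prof, 2))
  class(fake) <- c("hh_series", "data.frame")
  ph <- detect_phases(fake)
  expect_equal(ph$restoration_onset, peak_tod)
  # zero across-day variance: the threshold is the 02:00-08:00 window mean
  expect_equal(ph$maintenance_threshold, mean(avp_prof[121:480]))
  # maintenance onset = first minute after the peak at or below threshold
  ord <- ((peak_tod + seq_len(1440)) %% 1440)
  expected <- ord[which(avp_prof[ord + 1] <= ph$maintenance_threshold)[1]]
  expect_equal(ph$maintenance_onset, expected)
})

test_that("summaries convert to per-100 g and aggregate per day", {
  p <- hh_params()
  s <- simulate_hh(p, days = 2, seed = 4)
  sm <- summarize_hh(s, p)
  expect_equal(nrow(sm$daily), 2)
  day0 <- s$t_min < 1440
  expect_equal(sm$daily$ecf_v_per100g[1], mean(s$ecf_v[day0]) / 2.55)
  expect_equal(sm$daily$urine_ml_per100g[1], sum(s$urine_flow[day0]) / 2.55)
  expect_equal(sm$daily$intake_ml_per100g[1], sum(s$intake_ml[day0]) / 2.55)
  expect_equal(unname(sm$mean["ecf_na_conc"]), mean(s$na_conc))
  # sleeping / waking split covers the whole day
  expect_equal(sum(sm$periods[, "intake_ml_per_day"]) * 2, sum(s$intake_ml))
})

test_that("period statistics summarise an arbitrary span", {
  p <- hh_params()
  s <- simulate_hh(p, days = 1, seed = 9)
  ps <- period_stats(s, 0, 240, p)
  sel <- s$t_min < 240
  expect_equal(unname(ps["mean_na_conc"]), mean(s$na_conc[sel]))
  expect_equal(unname(ps["urine_ml_per100g"]), sum(s$urine_flow[sel]) / 2.55)
  expect_equal(unname(ps["end_na_conc"]), s$na_conc[240])
  expect_error(period_stats(s, 5000, 6000, p), "empty")
})

test_that("factor bounds hold over a full simulated day", {
  s <- simulate_hh(hh_params(), days = 1, seed = 6)
  expect_true(all(s$ald >= 0.2 & s$ald <= 1))
  expect_true(all(s$anp >= 1))
  expect_true(all(s$avp >= 0))
  expect_true(all(s$stomach_v <= 5 + 1e-9))
  expect_true(all(s$ecf_v > 0 & s$icf_v > 0))
})
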