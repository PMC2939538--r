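test_that("saline challenge infuses exactly 1 mmol over 10 minutes", {
  p <- hh_params()
  prot <- saline_challenge(days = 2)
  sched <- osmoreg:::compile_protocol(prot, p)
  expect_equal(sum(sched$infusion_na), 1.0)
  active <- which(sched$infusion_na > 0)
  expect_length(active, 10)
  expect_equal(unique(sched$infusion_na[active]), 0.1)
  # default start: 10:00 of the last day (sleeping period)
  expect_equal(active[1], 1440 + 120 + 1)
  # water is conserved: only sodium enters
  s <- simulate_hh(p, prot, seed = 5)
  expect_equal(ledger_errors(s, p)$water, 0, tolerance = 1e-9)
  expect_error(saline_challenge(duration_min = 0), "duration")
})

test_that("furosemide protocol gates water and schedules both injections", {
  p <- hh_params()
  prot <- furosemide_challenge(days = 2)
  sched <- osmoreg:::compile_protocol(prot, p)
  expect_equal(sched$furo_inj, c(1440, 1560))
  # minute indices are 1-based: minute m is row m+1
  expect_false(sched$water_access[1440 + 239 + 1])
  expect_true(sched$water_access[1440 + 241 + 1])
  expect_true(all(sched$water_access[1:1440]))      # day 0 is control
  expect_true(is.na(sched$na_override[1440 + 100])) # two-bottle until 12:00
  expect_equal(sched$na_override[1440 + 241], 11)
})

test_that("furosemide output follows the table and expires at the horizon", {
  p <- hh_params()
  out0 <- furosemide_output(0, p)
  expect_true(out0$active)
  expect_equal(out0$flow_ul_100g, unname(p$furosemide_flow_table[1, 2]))
  out15 <- furosemide_output(15, p)
  expect_equal(out15$flow_ul_100g, 28)
  expect_equal(furosemide_output(22.5, p)$flow_ul_100g, (28 + 26) / 2)
  beyond <- furosemide_output(241, p)
  expect_false(beyond$active)
  expect_equal(beyond$flow_ul_100g, 0)
  # the two-injection 4-h cumulative urine is the calibration target
  s <- simulate_hh(p, furosemide_challenge(days = 2), seed = 1)
  ur4 <- sum(s$urine_flow[s$t_min >= 1440 & s$t_min < 1680]) / 2.55
  expect_equal(ur4, 4.1, tolerance = 0.02)
  # urine sodium concentration during the diuresis stays in the cited band
  during <- s$furo_active == 1 & s$urine_flow > 0
  expect_true(all(s$urine_na_conc[during] >= 60 &
                  s$urine_na_conc[during] <= 120))
})

test_that("kidney override returns to normal after the diuresis", {
  p <- hh_params()
  s <- simulate_hh(p, furosemide_challenge(days = 2), seed = 1)
  # the second injection's table expires 360 min after 10:00 = 16:00
  expect_true(all(s$furo_active[s$t_min >= 1440 + 481] == 0))
  expect_true(all(s$furo_active[s$t_min >= 1440 & s$t_min <= 1440 + 360] == 1))
})

test_that("an empty protocol reproduces the control run exactly", {
  p <- hh_params()
  a <- simulate_hh(p, hh_protocol(2), seed = 11)
  b <- simulate_hh(p, days = 2, seed = 11)
  expect_identical(a$na_conc, b$na_conc)
  expect_identical(a$avp, b$avp)
})

test_that("protocol construction validates its events", {
  expect_error(add_event(hh_protocol(1), 2000, "forced_drink"))
  expect_error(add_event(hh_protocol(1), 10, "na_infusion",
                         total_mmol = -1, duration_min = 10), "positive")
  prot <- add_event(add_event(hh_protocol(1), 500, "forced_drink"),
                    100, "water_access", on = FALSE)
  starts <- vapply(prot$events, `[[`, numeric(1), "start_min")
  expect_equal(starts, sort(starts))  # kept time-ordered
})
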