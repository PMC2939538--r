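test_that("need-induced drinking triggers at 4% and latches to satiety", {
  p <- hh_params()
  s <- init_state(p)
  # 146 exceeds the 145.6 threshold; 145 does not
  s$ecf_na <- 146 * s$ecf_v / 1000
  s <- rule1_need(146, 140, s, p)
  expect_true(s$need_active)
  s2 <- init_state(p)
  s2$ecf_na <- 145 * s2$ecf_v / 1000
  s2 <- rule1_need(145, 140, s2, p)
  expect_false(s2$need_active)
  # once triggered it persists at intermediate concentrations
  s$ecf_na <- 143 * s$ecf_v / 1000
  s <- rule1_need(143, 140, s, p)
  expect_true(s$need_active)
  # and releases when the anticipated concentration reaches the set-point
  s$ecf_na <- 139.5 * s$ecf_v / 1000
  s <- rule1_need(139.5, 140, s, p)
  expect_false(s$need_active)
})

test_that("the anticipated concentration counts water still in the gut", {
  p <- hh_params()
  s <- init_state(p)
  expect_equal(anticipated_na_conc(s, p), ecf_na_conc(s), tolerance = 1e-9)
  # dehydrate, then load the stomach: anticipation sits between the
  # current concentration and the set-point
  s <- equilibrate_water(apply_fluxes(s, -8, 0), p)
  conc_dry <- ecf_na_conc(s)
  s_full <- ingest(s, 5, 0, p)
  ant <- anticipated_na_conc(s_full, p)
  expect_lt(ant, conc_dry)
  expect_gt(conc_dry, 140)
})

test_that("unregulated drinking probability peaks at 02:00, dips at 14:00", {
  tod <- 0:1439
  prob <- rule2_probability(tod, p_base = 0.02, amplitude = 0.5)
  expect_equal(tod[which.max(prob)], 120)
  expect_equal(tod[which.min(prob)], 840)
  expect_true(all(prob >= 0))
  # zero amplitude gives a flat profile
  expect_equal(rule2_probability(tod, 0.02, 0), rep(0.02, 1440))
  # expectation identity: the sinusoid integrates out over a full day
  expect_equal(sum(rule2_probability(tod, 0.02, 0.5)) * 2, 0.02 * 1440 * 2,
               tolerance = 1e-9)
  expect_error(rule2_probability(-1), "1440")
})

test_that("intake decisions follow rule precedence and protocol gating", {
  p <- hh_params()
  # need-induced dominates and delivers distilled water
  s <- init_state(p)
  s$ecf_na <- 150 * s$ecf_v / 1000
  d <- decide_intake(s, p, 600, u = 0)
  expect_equal(d$kind, "need_induced")
  expect_equal(d$na_conc, 0)
  expect_equal(d$volume, p$drinking$ingestion_rate_ml_min)
  # normal sodium with a winning draw starts a sodium-water bout
  s2 <- init_state(p)
  s2$ecf_na <- 141 * s2$ecf_v / 1000
  d2 <- decide_intake(s2, p, 120, u = 0)
  expect_equal(d2$kind, "unregulated")
  expect_equal(d2$na_conc, 50)
  # a losing draw yields no intake
  d3 <- decide_intake(s2, p, 120, u = 0.999999)
  expect_equal(d3$kind, "none")
  expect_equal(d3$volume, 0)
  # above the unregulated set-point no bout starts even with u = 0
  s4 <- init_state(p)
  s4$ecf_na <- 144 * s4$ecf_v / 1000
  expect_equal(decide_intake(s4, p, 120, u = 0)$kind, "none")
  # gated water access blocks everything, thirsty or not
  expect_equal(decide_intake(s, p, 600, water_access = FALSE, u = 0)$kind,
               "none")
  # the stomach-full lock suspends drinking
  s5 <- s
  s5$drinking_locked <- TRUE
  expect_equal(decide_intake(s5, p, 600, u = 0)$kind, "none")
})

test_that("hypovolemic thirst opens the sodium gate and latches", {
  p <- hh_params()
  s <- init_state(p)
  # low sodium normally closes the gate...
  s$ecf_na <- 137 * s$ecf_v / 1000
  s <- equilibrate_water(s, p)
  expect_equal(decide_intake(s, p, 120, u = 0)$kind, "none")
  # ...but a deep ECF deficit overrides it
  s2 <- init_state(p)
  s2 <- apply_fluxes(s2, -7, -7 * 0.137)   # lose ~12% ECF, near-isotonic
  expect_gt((58.65 - s2$ecf_v) / 58.65, p$hypovolemia_thirst_frac)
  d <- decide_intake(s2, p, 120, u = 0)
  expect_equal(d$kind, "unregulated")
  expect_true(d$state$hypovolemic)
})

test_that("drinking decisions are reproducible bit for bit given a seed", {
  p <- hh_params()
  a <- simulate_hh(p, days = 1, seed = 42)
  b <- simulate_hh(p, days = 1, seed = 42)
  expect_identical(a$intake_ml, b$intake_ml)
  expect_identical(a$na_conc, b$na_conc)
  c <- simulate_hh(p, days = 1, seed = 43)
  expect_false(identical(a$intake_ml, c$intake_ml))
})

test_that("most unregulated bouts fall in the waking period", {
  s <- control_20d()
  unreg <- s$intake_kind == 2 & s$intake_ml > 0
  waking <- s$tod < 480 | s$tod >= 1200
  expect_gt(sum(unreg & waking) / sum(unreg), 0.5)
  # rule separation: need-induced water carries no sodium in control runs,
  # unregulated bouts never start above the 4% threshold
  need <- s$intake_kind == 1 & s$intake_ml > 0
  expect_equal(sum(s$intake_na[need]), 0)
})
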