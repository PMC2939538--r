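test_that("state initialisation scales volumes by body weight", {
  p <- hh_params()
  s <- init_state(p)
  expect_equal(s$ecf_v, 58.65)
  expect_equal(s$icf_v, 117.3)
  expect_equal(s$ecf_na, 8.211)
  expect_equal(ecf_na_conc(s), 140)
  # per-100 g identity
  s100 <- init_state(hh_params(weight = 100))
  expect_equal(s100$ecf_v, 23)
  expect_equal(s100$icf_v, 46)
  # digestive compartments start empty, AVP at its initial value
  expect_equal(s$stomach_v + s$intestine_v, 0)
  expect_equal(s$avp, 1)
  # the fixed ICF osmole content cancels the gradient at t = 0
  expect_equal(effective_ecf_osmolality(ecf_na_conc(s), p$osmole_correction),
               s$icf_osmoles / s$icf_v * 1000)
})

test_that("parameter validation rejects unphysiological values", {
  expect_error(hh_params(na_clearance = -1), "positive")
  expect_error(hh_params(weight = 0), "positive")
  expect_error(hh_params(urine_flow_max = 5), "exceed")
  expect_error(hh_params(drink_threshold_frac = 1.5), "\\[0, 1\\]")
  expect_error(hh_params(nonsense = 1), "unknown parameter")
  bad_tab <- cbind(x = c(1, 0), y = c(0, 1))
  expect_error(hh_params(ald_volume_table = bad_tab), "increasing")
})

test_that("effective osmolality counts the anion and the correction", {
  expect_equal(effective_ecf_osmolality(140, 14), 294)
  expect_equal(effective_ecf_osmolality(137.5, 14), 289)
  expect_equal(effective_ecf_osmolality(0, 14), 14)
})

test_that("osmotic equilibration matches an independent root-finder", {
  p <- hh_params()
  base <- init_state(p)
  # baseline is a fixed point
  eq <- equilibrate_water(base, p)
  expect_equal(eq$ecf_v, base$ecf_v, tolerance = 1e-12)
  # adding 1 mmol sodium draws water out of the cells (frozen oracle values)
  s <- apply_fluxes(base, 0, 1)
  s <- equilibrate_water(s, p)
  expect_equal(s$ecf_v, 63.148555, tolerance = 1e-6)
  expect_equal(s$icf_v, 112.801445, tolerance = 1e-6)
  expect_equal(ecf_na_conc(s), 145.862403, tolerance = 1e-6)
  expect_lt(1 - s$icf_v / base$icf_v, 0.04)  # ~3.8% cell shrink
  # removing 5 ml of water shrinks both compartments
  s2 <- equilibrate_water(apply_fluxes(base, -5, 0), p)
  expect_equal(s2$ecf_v, 56.930265, tolerance = 1e-6)
  expect_lt(s2$icf_v, base$icf_v)
  expect_gt(ecf_na_conc(s2), 140)
  # 100 random physiological states: closed form == uniroot oracle, and the
  # residual gradient is below 1e-9 mosmol/L
  set.seed(99)
  for (i in 1:100) {
    st <- base
    st$ecf_na <- runif(1, 5, 12)
    total <- runif(1, 140, 210)
    st$ecf_v <- total * runif(1, 0.2, 0.5)
    st$icf_v <- total - st$ecf_v
    out <- equilibrate_water(st, p)
    expect_equal(out$ecf_v,
                 osmotic_oracle_ecf(st$ecf_na, st$icf_osmoles, total,
                                    p$osmole_correction),
                 tolerance = 1e-9)
    grad <- 2000 * out$ecf_na / out$ecf_v + p$osmole_correction -
      1000 * out$icf_osmoles / out$icf_v
    expect_lt(abs(grad), 1e-9)
    # idempotence and conservation
    twice <- equilibrate_water(out, p)
    expect_equal(twice$ecf_v, out$ecf_v, tolerance = 1e-12)
    expect_equal(out$ecf_v + out$icf_v, total, tolerance = 1e-12)
  }
})

test_that("apply_fluxes adds to the ECF only and guards the volume", {
  p <- hh_params()
  s <- init_state(p)
  s1 <- apply_fluxes(s, 1, 0)
  expect_equal(s1$ecf_v + s1$icf_v, s$ecf_v + s$icf_v + 1)
  expect_equal(s1$ecf_na, s$ecf_na)
  s2 <- apply_fluxes(s, 0, 1)
  expect_equal(s2$ecf_na, 9.211)
  expect_error(apply_fluxes(s, -60, 0), "non-positive")
  # the constant insensible flux accumulates to -15.55 ml/day
  expect_equal(p$unregulated_balance_flux * 1440, -15.552)
})
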