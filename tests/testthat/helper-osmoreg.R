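# Shared fixtures. Long runs are memoised so several test files can reuse
# them without re-simulating.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

control_20d <- function(seed = 1) {
  cached_run(paste0("control20_", seed),
             simulate_hh(hh_params(), days = 20, seed = seed))
}

# independent numeric oracle for the osmotic equilibrium: root of the
# gradient by uniroot, nothing shared with the package's closed form
osmotic_oracle_ecf <- function(na, icf_osmoles, total, correction) {
  g <- function(v) 2000 * na / v + correction -
    1000 * icf_osmoles / (total - v)
  stats::uniroot(g, c(1e-9, total - 1e-9), tol = 1e-12)$root
}

# water/sodium ledgers of a simulated series against its external fluxes
ledger_errors <- function(series, params) {
  total_w <- series$ecf_v + series$icf_v + series$stomach_v +
    series$intestine_v
  total_na <- series$ecf_na_content <- NULL
  gut_na <- series$stomach_na + series$intestine_na
  body_na <- series$na_conc * series$ecf_v / 1000 + gut_na
  init <- init_state(params)
  w0 <- init$ecf_v + init$icf_v
  na0 <- init$ecf_na
  dw <- diff(c(w0, total_w))
  dna <- diff(c(na0, body_na))
  expected_dw <- series$intake_ml - series$urine_flow +
    params$unregulated_balance_flux
  expected_dna <- series$intake_na + series$infusion_na - series$urine_na
  list(water = max(abs(dw - expected_dw)),
       sodium = max(abs(dna - expected_dna)))
}
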