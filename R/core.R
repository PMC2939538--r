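#' Initialise the body-fluid state
#'
#' Creates the per-minute mutable state of the simulation from the
#' parameter set. Compartment volumes are scaled from their per-100 g
#' values by body weight; the extracellular sodium content follows from
#' the initial concentration; the intracellular compartment is assigned a
#' fixed effective osmole content calibrated so that the osmotic gradient
#' at time zero is exactly zero (see [equilibrate_water()]). Digestive
#' compartments start empty.
#'
#' @param params an [hh_params()] object.
#' @return An object of class `hh_state`: a named list holding the clock
#'   (`t_min`, minute 0 = 08:00, start of the sleeping period), compartment
#'   volumes (`ecf_v`, `icf_v`, ml), solute contents (`ecf_na`, mmol;
#'   `icf_osmoles`, mosmol), circulating AVP (`avp`, pg/ml) and its
#'   pre-modulation controller level (`avp_ctrl`), stomach and intestine
#'   water/sodium, and the behavioural flags (`drinking_locked`,
#'   `need_active`, `unreg_remaining`).
#' @examples
#' s <- init_state(hh_params())
#' s$ecf_v    # 58.65 ml for a 255 g rat
#' ecf_na_conc(s)
#' @export
init_state <- function(params) {
  stopifnot(inherits(params, "hh_params"))
  scale <- params$weight / 100
  ecf_v <- params$ecf_v_init_per100g * scale
  icf_v <- params$icf_v_init_per100g * scale
  ecf_na <- params$ecf_na_conc_init * ecf_v / 1000
  osm_ecf <- effective_ecf_osmolality(params$ecf_na_conc_init,
                                      params$osmole_correction)
  # fixed effective ICF osmole content (mosmol), zero gradient at t = 0
  icf_osmoles <- osm_ecf * icf_v / 1000
  s <- list(
    t_min = 0L,
    ecf_v = ecf_v,
    icf_v = icf_v,
    ecf_na = ecf_na,
    icf_osmoles = icf_osmoles,
    avp = params$avp_init,
    avp_ctrl = params$avp_init,
    stomach_v = 0, stomach_na = 0,
    intestine_v = 0, intestine_na = 0,
    drinking_locked = FALSE,
    need_active = FALSE,
    hypovolemic = FALSE,
    unreg_remaining = 0,
    forced_remaining = 0
  )
  class(s) <- "hh_state"
  s
}

#' Extracellular sodium concentration
#'
#' @param state an `hh_state`.
#' @return Sodium concentration, mmol/L (`ecf_na / ecf_v * 1000`).
#' @export
ecf_na_conc <- function(state) {
  if (state$ecf_v <= 0) stop("ECF volume is not positive")
  state$ecf_na / state$ecf_v * 1000
}

#' Effective extracellular osmolality
#'
#' Sodium and its accompanying anion (factor 2) plus a fixed correction
#' for the osmotic contribution of sugars, proteins and urea.
#'
#' @param na_conc sodium concentration, mmol/L.
#' @param correction non-electrolyte contribution, mosmol/L.
#' @return Effective osmolality, mosmol/L.
#' @examples
#' effective_ecf_osmolality(140, 14)  # 294
#' @export
effective_ecf_osmolality <- function(na_conc, correction = 14) {
  stopifnot(all(na_conc >= 0))
  2 * na_conc + correction
}

# Closed-form osmotic equilibrium: find the ECF volume V_E in (0, total)
# such that 2000 * na / V_E + corr = 1000 * osm_icf / (total - V_E).
# Reduces to corr * V^2 + (2000 na + 1000 osm - corr total) V
#            - 2000 na total = 0; the product of the roots is negative, so
# exactly one root is positive, and it lies below `total`.
osmotic_equilibrium_ecf <- function(ecf_na, icf_osmoles, total_water,
                                    correction) {
  a <- correction
  b <- 2000 * ecf_na + 1000 * icf_osmoles - correction * total_water
  cc <- -2000 * ecf_na * total_water
  if (ecf_na <= 0) stop("osmotic equilibrium requires positive ECF sodium")
  v <- (-b + sqrt(b * b - 4 * a * cc)) / (2 * a)
  if (!is.finite(v) || v <= 0 || v >= total_water)
    stop("no physiological osmotic equilibrium in (0, total water)")
  v
}

#' Redistribute water osmotically between ICF and ECF
#'
#' Moves water between the intracellular and extracellular compartments,
#' within one time step, until the effective extracellular osmolality
#' (2 [Na+] + correction) equals the intracellular osmolality
#' (`icf_osmoles / icf_v`). Total water and all solute contents are
#' conserved; the fixed intracellular osmole content is untouched. The
#' sub-minute kinetics of trans-membrane exchange justify treating the
#' redistribution as instantaneous at this resolution.
#'
#' @param state an `hh_state`.
#' @param params an [hh_params()] object.
#' @return The state with `ecf_v` and `icf_v` at osmotic equilibrium
#'   (residual gradient below 1e-9 mosmol/L).
#' @export
equilibrate_water <- function(state, params) {
  total <- state$ecf_v + state$icf_v
  v_e <- osmotic_equilibrium_ecf(state$ecf_na, state$icf_osmoles, total,
                                 params$osmole_correction)
  state$ecf_v <- v_e
  state$icf_v <- total - v_e
  state
}

#' Apply external water and sodium fluxes to the ECF
#'
#' All digestive, renal, infusion and insensible fluxes enter or leave the
#' body through the extracellular compartment; callers follow with
#' [equilibrate_water()] to redistribute the water osmotically.
#'
#' @param state an `hh_state`.
#' @param d_water_ecf water added to the ECF, ml (negative = loss).
#' @param d_na_ecf sodium added to the ECF, mmol.
#' @return The updated state.
#' @export
apply_fluxes <- function(state, d_water_ecf = 0, d_na_ecf = 0) {
  ecf_v <- state$ecf_v + d_water_ecf
  if (ecf_v <= 0)
    stop(sprintf(paste0("flux of %.4f ml would drive the ECF volume ",
                        "non-positive at minute %d"),
                 d_water_ecf, state$t_min))
  state$ecf_v <- ecf_v
  state$ecf_na <- max(0, state$ecf_na + d_na_ecf)
  state
}

#' @export
print.hh_state <- function(x, ...) {
  cat(sprintf("hh_state @ minute %d\n", x$t_min))
  cat(sprintf("  ECF %.2f ml  [Na+] %.2f mmol/L   ICF %.2f ml\n",
              x$ecf_v, ecf_na_conc(x), x$icf_v))
  cat(sprintf("  AVP %.2f pg/ml   stomach %.2f ml  intestine %.2f ml\n",
              x$avp, x$stomach_v, x$intestine_v))
  invisible(x)
}
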