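#' Model parameters for the rat hydromineral simulator
#'
#' Builds the full parameter set of the simulator. Defaults are the
#' physiological values for a 255 g laboratory rat; every argument can be
#' overridden. All internal units are ml, mmol, pg/ml and minutes;
#' concentrations are surfaced in mmol/L.
#'
#' The two-compartment body-fluid model keeps the intracellular potassium
#' concentration fixed and represents the intracellular compartment by a
#' constant effective osmole content calibrated at start-up, so that water
#' shifts between compartments are driven purely by extracellular sodium.
#' Initial compartment volumes are given per 100 g body weight and scaled
#' by `weight / 100`.
#'
#' Several inputs the model needs are only available in the literature as
#' dose-response curves; they are shipped here as editable piecewise-linear
#' lookup tables (ordered (x, y) knot matrices) with calibrated default
#' knots, not transcriptions:
#' \describe{
#'   \item{`ald_volume_table`}{fractional ECF volume deficit below the
#'     set-point (x) to plasma aldosterone, ng/100 ml (y).}
#'   \item{`ald_factor_table`}{aldosterone, ng/100 ml (x) to multiplicative
#'     sodium-excretion factor (y), bounded to [0.2, 1].}
#'   \item{`anp_volume_table`}{fractional ECF volume expansion (x) to plasma
#'     atrial natriuretic peptide, pg/ml (y), capped at `anp_cap`.}
#'   \item{`anp_factor_table`}{ANP, pg/ml (x) to multiplicative natriuresis
#'     factor (y), always >= 1.}
#'   \item{`furosemide_flow_table`}{minutes since a furosemide injection (x)
#'     to urine flow, ul/min/100 g (y).}
#'   \item{`furosemide_na_table`}{minutes since injection (x) to urine
#'     sodium concentration, mmol/L (y).}
#' }
#'
#' @param weight body mass, g.
#' @param icf_k_conc intracellular potassium concentration, mmol/L (held
#'   constant).
#' @param ecf_na_conc_init initial extracellular sodium concentration,
#'   mmol/L; also the drinking set-point.
#' @param avp_init initial plasma AVP, pg/ml.
#' @param ecf_v_init_per100g,icf_v_init_per100g initial extracellular and
#'   intracellular volumes, ml per 100 g body weight.
#' @param na_clearance renal sodium clearance, ml/min (whole animal).
#' @param osmole_correction non-sodium plasma osmotic contribution (sugar,
#'   protein, urea), mosmol/L.
#' @param drink_threshold_frac fractional excess of extracellular sodium
#'   over the set-point that triggers need-induced drinking.
#' @param rule2_setpoint upper sodium concentration, mmol/L, at or below
#'   which unregulated (need-free) drinking is permitted.
#' @param rule2_lower lower sodium concentration, mmol/L, below which
#'   unregulated drinking no longer starts ("normal or slightly lower":
#'   once the concentration has fallen clearly below the set-point there
#'   is no drive left to drink); calibrated default.
#' @param hypovolemia_thirst_frac fractional ECF volume deficit beyond
#'   which hypovolemic thirst overrides the sodium-concentration gates on
#'   unregulated drinking (volume-depleted animals drink whatever water is
#'   available regardless of plasma sodium); the override latches until
#'   the deficit has recovered to 1/2.5 of this threshold.
#' @param stomach_full_ml stomach capacity at which drinking stops, ml.
#' @param stomach_comfort_ml stomach volume below which drinking may
#'   resume, ml.
#' @param unregulated_balance_flux net non-renal water flux (sweat, faeces,
#'   food and metabolic water), ml/min; negative means net loss.
#' @param urine_flow_basal_avp AVP level, pg/ml, producing the basal urine
#'   flow.
#' @param urine_flow_basal basal urine flow, ul/min/100 g.
#' @param urine_flow_max maximal (AVP-free) urine flow, ul/min/100 g.
#' @param avp_clearance_frac_per_min fraction of circulating AVP cleared
#'   per minute when secretion is falling.
#' @param circadian_avp list with elements `start_min`, `nadir_min`,
#'   `restored_min` (minutes past midnight) and `depth` (fractional
#'   reduction at the nadir) describing the pre-sleep AVP reduction.
#' @param drinking list of drinking-behaviour constants: `bout_volume_ml`,
#'   `ingestion_rate_ml_min`, `unregulated_na_conc` (mmol/L),
#'   `p_base` (mean per-minute probability of starting an unregulated
#'   bout), `p_amplitude` (relative amplitude of its circadian sinusoid)
#'   and `p_max_min` (minute past midnight of maximal probability).
#' @param gut list of first-order digestive rate constants (per minute):
#'   `k_stomach_intestine` (gastric emptying), `k_stomach_ecf` (passive
#'   gastric water diffusion), `k_intestine_ecf` (intestinal water
#'   absorption) and `k_na_active` (active intestinal sodium absorption).
#' @param ald_volume_table,ald_factor_table,anp_volume_table,anp_factor_table
#'   lookup tables, see Details.
#' @param anp_cap maximal plasma ANP, pg/ml.
#' @param furosemide_flow_table,furosemide_na_table furosemide urine
#'   time-course tables, see Details.
#' @param tap_water_na_conc sodium concentration of tap water, mmol/L.
#' @param ... overrides collected by name; unknown names are an error.
#'
#' @return An object of class `hh_params`: a validated named list.
#' @examples
#' p <- hh_params()
#' p$weight
#' hh_params(weight = 100)$weight
#' @export
hh_params <- function(weight = 255,
                      icf_k_conc = 112,
                      ecf_na_conc_init = 140,
                      avp_init = 1,
                      ecf_v_init_per100g = 23,
                      icf_v_init_per100g = 46,
                      na_clearance = 0.0086,
                      osmole_correction = 14,
                      drink_threshold_frac = 0.04,
                      rule2_setpoint = 142,
                      rule2_lower = 139.85,
                      hypovolemia_thirst_frac = 0.06,
                      stomach_full_ml = 5.0,
                      stomach_comfort_ml = 3.1,
                      unregulated_balance_flux = -0.0108,
                      urine_flow_basal_avp = 2.3,
                      urine_flow_basal = 6,
                      urine_flow_max = 138,
                      avp_clearance_frac_per_min = 0.15,
                      circadian_avp = list(start_min = 120, nadir_min = 480,
                                           restored_min = 660, depth = 0.30),
                      drinking = list(bout_volume_ml = 1,
                                      ingestion_rate_ml_min = 1,
                                      unregulated_na_conc = 50,
                                      p_base = 0.24,
                                      p_amplitude = 1.0,
                                      p_max_min = 120),
                      gut = list(k_stomach_intestine = 0.018,
                                 k_stomach_ecf = 0.003,
                                 k_intestine_ecf = 0.045,
                                 k_na_active = 0.04),
                      ald_volume_table = cbind(x = c(0, 0.02, 0.05, 0.10),
                                               y = c(0, 40, 120, 200)),
                      ald_factor_table = cbind(x = c(0, 200),
                                               y = c(1, 0.2)),
                      anp_volume_table = cbind(x = c(0, 0.05, 0.10),
                                               y = c(0, 700, 2000)),
                      anp_factor_table = cbind(x = c(0, 1000, 2000),
                                               y = c(1, 1.35, 1.7)),
                      anp_cap = 2000,
                      furosemide_flow_table =
                        cbind(x = c(0, 15, 30, 60, 90, 120, 180, 240),
                              y = c(7, 28, 26, 19, 11, 6, 1.7, 0)),
                      furosemide_na_table =
                        cbind(x = c(0, 30, 60, 120, 240),
                              y = c(90, 85, 80, 70, 65)),
                      tap_water_na_conc = 0.43,
                      ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown parameter(s): ", paste(names(extra), collapse = ", "))
  p <- list(
    weight = weight,
    icf_k_conc = icf_k_conc,
    ecf_na_conc_init = ecf_na_conc_init,
    avp_init = avp_init,
    ecf_v_init_per100g = ecf_v_init_per100g,
    icf_v_init_per100g = icf_v_init_per100g,
    na_clearance = na_clearance,
    osmole_correction = osmole_correction,
    drink_threshold_frac = drink_threshold_frac,
    rule2_setpoint = rule2_setpoint,
    rule2_lower = rule2_lower,
    hypovolemia_thirst_frac = hypovolemia_thirst_frac,
    stomach_full_ml = stomach_full_ml,
    stomach_comfort_ml = stomach_comfort_ml,
    unregulated_balance_flux = unregulated_balance_flux,
    urine_flow_basal_avp = urine_flow_basal_avp,
    urine_flow_basal = urine_flow_basal,
    urine_flow_max = urine_flow_max,
    avp_clearance_frac_per_min = avp_clearance_frac_per_min,
    circadian_avp = circadian_avp,
    drinking = drinking,
    gut = gut,
    ald_volume_table = ald_volume_table,
    ald_factor_table = ald_factor_table,
    anp_volume_table = anp_volume_table,
    anp_factor_table = anp_factor_table,
    anp_cap = anp_cap,
    furosemide_flow_table = furosemide_flow_table,
    furosemide_na_table = furosemide_na_table,
    tap_water_na_conc = tap_water_na_conc
  )
  class(p) <- "hh_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  chk_pos <- function(name) {
    v <- p[[name]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", name, "' must be a single positive number",
           call. = FALSE)
  }
  for (nm in c("weight", "icf_k_conc", "ecf_na_conc_init", "avp_init",
               "ecf_v_init_per100g", "icf_v_init_per100g", "na_clearance",
               "osmole_correction", "rule2_setpoint", "stomach_full_ml",
               "stomach_comfort_ml", "urine_flow_basal_avp",
               "urine_flow_basal", "urine_flow_max", "anp_cap"))
    chk_pos(nm)
  chk_frac <- function(name, v) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("parameter '", name, "' must lie in [0, 1]", call. = FALSE)
  }
  chk_frac("drink_threshold_frac", p$drink_threshold_frac)
  chk_frac("hypovolemia_thirst_frac", p$hypovolemia_thirst_frac)
  chk_frac("avp_clearance_frac_per_min", p$avp_clearance_frac_per_min)
  chk_frac("circadian depth", p$circadian_avp$depth)
  if (p$urine_flow_max <= p$urine_flow_basal)
    stop("urine_flow_max must exceed urine_flow_basal", call. = FALSE)
  if (p$stomach_comfort_ml >= p$stomach_full_ml)
    stop("stomach_comfort_ml must be below stomach_full_ml", call. = FALSE)
  if (!is.numeric(p$unregulated_balance_flux) ||
      length(p$unregulated_balance_flux) != 1L)
    stop("unregulated_balance_flux must be a single number", call. = FALSE)
  for (nm in c("ald_volume_table", "ald_factor_table", "anp_volume_table",
               "anp_factor_table", "furosemide_flow_table",
               "furosemide_na_table"))
    check_knot_table(p[[nm]], nm)
  d <- p$drinking
  if (d$bout_volume_ml <= 0 || d$ingestion_rate_ml_min <= 0 ||
      d$p_base < 0 || d$p_amplitude < 0 || d$p_amplitude > 1)
    stop("invalid drinking parameters", call. = FALSE)
  g <- p$gut
  if (any(unlist(g) < 0) ||
      g$k_stomach_intestine + g$k_stomach_ecf >= 1 ||
      g$k_intestine_ecf + g$k_na_active >= 1)
    stop("gut rate constants must be non-negative and sum below 1 per ",
         "compartment", call. = FALSE)
  invisible(p)
}

check_knot_table <- function(tab, name) {
  if (!is.matrix(tab) || ncol(tab) != 2L || nrow(tab) < 2L ||
      !is.numeric(tab) || anyNA(tab))
    stop("lookup table '", name, "' must be a numeric matrix with two ",
         "columns and at least two knots", call. = FALSE)
  if (is.unsorted(tab[, 1L], strictly = TRUE))
    stop("lookup table '", name, "' must have strictly increasing x knots",
         call. = FALSE)
  invisible(tab)
}

# Piecewise-linear table evaluation, clamped at both ends.
eval_table <- function(tab, x) {
  stats::approx(tab[, 1L], tab[, 2L], xout = x, rule = 2)$y
}

#' @export
print.hh_params <- function(x, ...) {
  cat("Rat hydromineral model parameters\n")
  cat(sprintf("  body weight:          %g g\n", x$weight))
  cat(sprintf("  initial ECF [Na+]:    %g mmol/L (set-point)\n",
              x$ecf_na_conc_init))
  cat(sprintf("  initial ECF/ICF vol:  %g / %g ml/100 g\n",
              x$ecf_v_init_per100g, x$icf_v_init_per100g))
  cat(sprintf("  Na+ clearance:        %g ml/min\n", x$na_clearance))
  cat(sprintf("  urine flow:           %g (max) / %g (at %g pg/ml AVP) ul/min/100 g\n",
              x$urine_flow_max, x$urine_flow_basal, x$urine_flow_basal_avp))
  cat(sprintf("  AVP clearance:        %g%%/min; circadian nadir -%g%%\n",
              100 * x$avp_clearance_frac_per_min,
              100 * x$circadian_avp$depth))
  cat(sprintf("  insensible balance:   %g ml/min\n",
              x$unregulated_balance_flux))
  invisible(x)
}
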