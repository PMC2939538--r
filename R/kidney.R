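#' AVP-dependent urine flow
#'
#' Urine flow falls monotonically with circulating AVP. The default form
#' is a hyperbolic decay `F(avp) = F_max / (1 + k avp)` per 100 g body
#' weight, with `F_max` the AVP-free maximal flow and `k` fixed so that
#' the curve passes exactly through the basal operating point
#' (`urine_flow_basal` at `urine_flow_basal_avp`).
#'
#' @param avp circulating AVP, pg/ml.
#' @param weight body weight, g.
#' @param params an [hh_params()] object.
#' @return Urine flow, ml/min (whole animal).
#' @examples
#' p <- hh_params()
#' urine_flow(0, 100, p)    # 0.138 ml/min: maximal flow
#' urine_flow(2.3, 100, p)  # 0.006 ml/min: basal flow
#' @export
urine_flow <- function(avp, weight, params) {
  stopifnot(all(avp >= 0))
  k <- (params$urine_flow_max / params$urine_flow_basal - 1) /
    params$urine_flow_basal_avp
  flow_ul_100g <- params$urine_flow_max / (1 + k * avp)
  flow_ul_100g * weight / 100 / 1000
}

#' Aldosterone sodium-retention factor
#'
#' Volume feedback promoting sodium retention under hypovolemia: the
#' fractional ECF volume deficit below the set-point maps to a plasma
#' aldosterone concentration (calibrated lookup table), which maps
#' linearly to a multiplicative factor on sodium excretion, from 1 (no
#' aldosterone) down to a floor of 0.2 (200 ng/100 ml).
#'
#' @param ecf_v current ECF volume, ml.
#' @param ecf_v0 set-point ECF volume, ml.
#' @param params an [hh_params()] object.
#' @return Factor in [0.2, 1]; exactly 1 when `ecf_v >= ecf_v0`.
#' @export
ald_factor <- function(ecf_v, ecf_v0, params) {
  stopifnot(ecf_v > 0, ecf_v0 > 0)
  if (ecf_v >= ecf_v0) return(1)
  deficit <- (ecf_v0 - ecf_v) / ecf_v0
  ald_conc <- eval_table(params$ald_volume_table, deficit)
  f <- eval_table(params$ald_factor_table, ald_conc)
  min(1, max(0.2, f))
}

#' Atrial-natriuretic-peptide natriuresis factor
#'
#' Volume feedback increasing sodium excretion under hypervolemia: the
#' fractional ECF volume expansion above the set-point maps to a plasma
#' ANP concentration (capped at `anp_cap` to avoid extrapolation error
#' under large volume changes), which maps to a multiplicative natriuresis
#' factor of at least 1.
#'
#' @inheritParams ald_factor
#' @return Factor >= 1; exactly 1 when `ecf_v <= ecf_v0`.
#' @export
anp_factor <- function(ecf_v, ecf_v0, params) {
  stopifnot(ecf_v > 0, ecf_v0 > 0)
  if (ecf_v <= ecf_v0) return(1)
  expansion <- (ecf_v - ecf_v0) / ecf_v0
  anp <- min(params$anp_cap, eval_table(params$anp_volume_table, expansion))
  max(1, eval_table(params$anp_factor_table, anp))
}

#' Renal sodium excretion rate
#'
#' Passive clearance of extracellular sodium modulated by the aldosterone
#' and ANP volume-feedback factors:
#' `Na_urine = [Na+] * C_Na * ALD_factor * ANP_factor` (mmol per minute).
#'
#' @param na_conc extracellular sodium concentration one minute before the
#'   current minute, mmol/L.
#' @param c_na sodium clearance, ml/min.
#' @param ald aldosterone factor, in [0.2, 1].
#' @param anp ANP factor, >= 1.
#' @return Sodium excretion, mmol/min.
#' @examples
#' sodium_excretion(140, 0.0086, 1, 1)  # 0.001204 mmol/min
#' @export
sodium_excretion <- function(na_conc, c_na, ald, anp) {
  stopifnot(na_conc >= 0, c_na >= 0, ald >= 0.2, ald <= 1, anp >= 1)
  (na_conc / 1000) * c_na * ald * anp
}

#' One minute of kidney output
#'
#' Composes the AVP-dependent urine flow with sodium excretion and the
#' volume-feedback factors. When a furosemide override is supplied (see
#' [furosemide_output()]), the diuretic's urine flow and urine sodium
#' concentration replace the regular kidney output for that minute.
#'
#' @param state an `hh_state`.
#' @param params an [hh_params()] object.
#' @param na_conc_prev ECF sodium concentration at the previous minute,
#'   mmol/L (defaults to the current concentration).
#' @param avp_prev circulating AVP at the previous minute, pg/ml
#'   (defaults to the current level).
#' @param override `NULL`, or a list with `flow_ul_100g` (ul/min/100 g)
#'   and `na_conc` (mmol/L) from the furosemide table.
#' @return A list of class `hh_renal`: `urine_water` (ml/min), `urine_na`
#'   (mmol/min), `urine_na_conc` (mmol/L), `ald_factor`, `anp_factor`.
#' @export
kidney_step <- function(state, params, na_conc_prev = ecf_na_conc(state),
                        avp_prev = state$avp, override = NULL) {
  ecf_v0 <- params$ecf_v_init_per100g * params$weight / 100
  ald <- ald_factor(state$ecf_v, ecf_v0, params)
  anp <- anp_factor(state$ecf_v, ecf_v0, params)
  if (!is.null(override)) {
    water <- override$flow_ul_100g * params$weight / 100 / 1000
    na <- water * override$na_conc / 1000
  } else {
    water <- urine_flow(avp_prev, params$weight, params)
    na <- sodium_excretion(na_conc_prev, params$na_clearance, ald, anp)
  }
  # a minute's output can never exceed what the ECF holds
  water <- min(water, 0.5 * state$ecf_v)
  na <- min(na, state$ecf_na)
  out <- list(urine_water = water, urine_na = na,
              urine_na_conc = if (water > 0) na / water * 1000 else 0,
              ald_factor = ald, anp_factor = anp)
  class(out) <- "hh_renal"
  out
}
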