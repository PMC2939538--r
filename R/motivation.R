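#' Need-induced drinking trigger (Rule 1)
#'
#' Need-induced intake of distilled water starts when the extracellular
#' sodium concentration exceeds the set-point by the drinking threshold
#' (default 4\%), and, once engaged, persists until the concentration is
#' restored to the set-point. The stomach-fullness lock suspends drinking
#' without cancelling the need.
#'
#' @param na_conc current ECF sodium concentration, mmol/L.
#' @param setpoint drinking set-point, mmol/L.
#' @param state an `hh_state` (supplies the latch `need_active` and the
#'   fullness lock).
#' @param params an [hh_params()] object.
#' Drinking is terminated on the *anticipated* concentration — the
#' equilibrium the body will reach once the water and sodium still in
#' transit through the gut have been absorbed (see
#' [anticipated_na_conc()]) — mimicking the pre-absorptive (oropharyngeal
#' and gastric) satiety signals that stop a real rat before the ingested
#' water has reached the plasma; terminating on the instantaneous
#' concentration instead would overshoot the set-point by the full
#' absorption lag.
#'
#' @return The state with an updated `need_active` latch; whether drinking
#'   proceeds this minute is `state$need_active && !state$drinking_locked`.
#' @export
rule1_need <- function(na_conc, setpoint, state, params) {
  threshold <- setpoint * (1 + params$drink_threshold_frac)
  if (na_conc > threshold) state$need_active <- TRUE
  if (state$need_active && anticipated_na_conc(state, params) <= setpoint)
    state$need_active <- FALSE
  state
}

#' Anticipated post-absorption sodium concentration
#'
#' The satiety/permission signal of the motivation module: the current
#' (osmoreceptor) sodium concentration plus the change the brain predicts
#' from absorbing the water and sodium still in transit through the gut,
#' assuming an intact body (osmotic redistribution between the
#' compartments). When the state is itself at osmotic equilibrium this
#' equals the concentration the body will actually reach once the gut
#' empties; when a protocol blocks intracellular exchange the prediction
#' is anchored on the real (elevated or depressed) concentration but
#' mis-estimates the dilution in transit -- the behavioural overshoot
#' that follows is a prediction of the model, not an artifact.
#'
#' @param state an `hh_state`.
#' @param params an [hh_params()] object.
#' @return Concentration, mmol/L.
#' @export
anticipated_na_conc <- function(state, params) {
  gut_w <- state$stomach_v + state$intestine_v
  gut_na <- state$stomach_na + state$intestine_na
  body_w <- state$ecf_v + state$icf_v
  eq_conc <- function(na, total) {
    na / osmotic_equilibrium_ecf(na, state$icf_osmoles, total,
                                 params$osmole_correction) * 1000
  }
  delta <- eq_conc(state$ecf_na + gut_na, body_w + gut_w) -
    eq_conc(state$ecf_na, body_w)
  ecf_na_conc(state) + delta
}

#' Circadian probability of unregulated drinking (Rule 2)
#'
#' Unregulated (need-free) drinking bouts start stochastically with a
#' per-minute probability following a translated sinusoid over the day,
#' maximal in the middle of the waking period (02:00) and minimal at
#' 14:00:
#' `p(t) = p_base * (1 + a * sin(2 pi (t - t0) / 1440))`
#' with the phase `t0` fixed by the time of the maximum.
#'
#' @param time_of_day minutes past midnight, in [0, 1440).
#' @param p_base mean per-minute bout probability.
#' @param amplitude relative amplitude `a` of the sinusoid, in [0, 1].
#' @param p_max_min minute past midnight of maximal probability.
#' @return Per-minute probability (vectorised over `time_of_day`).
#' @export
rule2_probability <- function(time_of_day, p_base = 0.24,
                              amplitude = 1.0, p_max_min = 120) {
  if (any(time_of_day < 0 | time_of_day >= 1440))
    stop("time_of_day must lie in [0, 1440)")
  phase <- p_max_min - 1440 / 4
  pmax(0, p_base * (1 + amplitude * sin(2 * pi * (time_of_day - phase) / 1440)))
}

#' Per-minute drinking decision
#'
#' Combines the two motivation rules into an intake command for the
#' current minute. Need-induced drinking (Rule 1) dominates and delivers
#' distilled water at the ingestion rate. Otherwise an ongoing unregulated
#' bout continues, or, when the sodium concentration is at or below the
#' unregulated set-point, a new bout of sodium-containing water may start
#' with probability [rule2_probability()] (an ECF volume deficit beyond
#' `hypovolemia_thirst_frac` opens the sodium gate regardless of the
#' concentration: hypovolemic thirst). Bouts span consecutive minutes
#' until the bout volume is delivered or the stomach is full. Water-access
#' gating by a protocol aborts everything.
#'
#' @param state an `hh_state`.
#' @param params an [hh_params()] object.
#' @param time_of_day minutes past midnight.
#' @param water_access logical; `FALSE` while the protocol withholds water.
#' @param na_override optional sodium concentration, mmol/L, of the only
#'   available drinking water (protocols such as the furosemide challenge
#'   replace both water sources by a single bottle); `NA` for the default
#'   two-bottle situation (distilled for need, `unregulated_na_conc` for
#'   unregulated bouts).
#' @param forced logical; start one additional (forced) bout this minute.
#' @param forced_volume volume of the forced bout, ml (defaults to the
#'   regular bout volume).
#' @param icf_block logical; osmotic exchange with the ICF is suspended
#'   (kept for interface symmetry; the anticipatory satiety signal is the
#'   brain's model of an intact body and deliberately ignores the block).
#' @param u uniform random draw for the Rule-2 start decision. The engine
#'   pre-draws one uniform per minute so that runs sharing a seed are
#'   driven by common random numbers: protocol comparisons (forced drink,
#'   blocked exchange, challenges) are then paired minute by minute.
#' @return A list of class `hh_intake`: `state` (updated latches and bout
#'   bookkeeping), `kind` (`"none"`, `"need_induced"` or `"unregulated"`),
#'   `volume` (ml to ingest this minute) and `na_conc` (mmol/L of that
#'   water).
#' @export
decide_intake <- function(state, params, time_of_day, water_access = TRUE,
                          na_override = NA_real_, forced = FALSE,
                          forced_volume = NULL, icf_block = FALSE,
                          u = stats::runif(1)) {
  d <- params$drinking
  none <- function(st) {
    out <- list(state = st, kind = "none", volume = 0, na_conc = 0)
    class(out) <- "hh_intake"
    out
  }
  # drinking decisions read the anticipated (gut-corrected) concentration:
  # the pre-absorptive signals that meter intake in the rat act on what has
  # been drunk, not on what has reached the plasma
  # the anticipatory signal is the brain's own model of an intact body:
  # it assumes osmotic exchange works even when a protocol blocks it, so
  # satiety mis-predicts under the blocked-exchange scenario (and the
  # behavioural overshoot that follows is a prediction, not an artifact)
  conc <- anticipated_na_conc(state, params)
  state <- rule1_need(ecf_na_conc(state), params$ecf_na_conc_init, state,
                      params)
  if (forced)
    state$forced_remaining <- state$forced_remaining +
      (if (is.null(forced_volume) || is.na(forced_volume))
         d$bout_volume_ml else forced_volume)
  if (!water_access) {
    state$unreg_remaining <- 0   # the interrupted bout does not resume
    state$forced_remaining <- 0
    return(none(state))
  }
  rate <- d$ingestion_rate_ml_min
  room <- params$stomach_full_ml - state$stomach_v
  if (state$need_active && !state$drinking_locked && room > 0) {
    vol <- min(rate, room)
    na <- if (is.na(na_override)) 0 else na_override
    out <- list(state = state, kind = "need_induced", volume = vol,
                na_conc = na)
    class(out) <- "hh_intake"
    return(out)
  }
  if (state$drinking_locked || room <= 0) return(none(state))
  # a forced (experimenter-administered) bout of the regular drinking
  # water is delivered ahead of any spontaneous drinking
  if (state$forced_remaining > 0) {
    vol <- min(rate, state$forced_remaining, room)
    state$forced_remaining <- state$forced_remaining - vol
    na <- if (is.na(na_override)) d$unregulated_na_conc else na_override
    out <- list(state = state, kind = "unregulated", volume = vol,
                na_conc = na)
    class(out) <- "hh_intake"
    return(out)
  }
  # hypovolemic thirst: a clear ECF volume deficit overrides the sodium
  # gates on unregulated drinking (a volume-depleted rat drinks whatever
  # water is available, regardless of plasma sodium); latched until the
  # volume is essentially restored
  ecf_v0 <- params$ecf_v_init_per100g * params$weight / 100
  deficit <- (ecf_v0 - state$ecf_v) / ecf_v0
  if (deficit > params$hypovolemia_thirst_frac) state$hypovolemic <- TRUE
  if (deficit < params$hypovolemia_thirst_frac / 2.5)
    state$hypovolemic <- FALSE
  gate_open <- state$hypovolemic ||
    (conc <= params$rule2_setpoint && conc >= params$rule2_lower)
  if (state$unreg_remaining <= 0 && gate_open) {
    p <- rule2_probability(time_of_day, d$p_base, d$p_amplitude, d$p_max_min)
    if (u < p)
      state$unreg_remaining <- d$bout_volume_ml
  }
  if (state$unreg_remaining > 0) {
    vol <- min(rate, state$unreg_remaining, room)
    state$unreg_remaining <- state$unreg_remaining - vol
    na <- if (is.na(na_override)) d$unregulated_na_conc else na_override
    out <- list(state = state, kind = "unregulated", volume = vol,
                na_conc = na)
    class(out) <- "hh_intake"
    return(out)
  }
  none(state)
}
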