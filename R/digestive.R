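#' Ingest water into the stomach
#'
#' Adds a volume of drinking water (and its sodium) to the stomach. If the
#' volume would exceed the stomach capacity the intake is truncated at
#' capacity. Reaching capacity engages the fullness lock, which stops
#' drinking until gastric emptying brings the stomach back below its
#' comfort volume (see [gut_step()]).
#'
#' @param state an `hh_state`.
#' @param volume volume to ingest, ml (>= 0).
#' @param na_conc sodium concentration of the ingested water, mmol/L.
#' @param params an [hh_params()] object.
#' @return The updated state; the volume actually ingested is available as
#'   attribute `"ingested"`.
#' @examples
#' s <- ingest(init_state(hh_params()), 2, 50, hh_params())
#' s$stomach_na  # 0.1 mmol
#' @export
ingest <- function(state, volume, na_conc, params) {
  stopifnot(volume >= 0, na_conc >= 0)
  room <- params$stomach_full_ml - state$stomach_v
  taken <- min(volume, max(0, room))
  state$stomach_v <- state$stomach_v + taken
  state$stomach_na <- state$stomach_na + taken * na_conc / 1000
  if (state$stomach_v >= params$stomach_full_ml - 1e-12)
    state$drinking_locked <- TRUE
  attr(state, "ingested") <- taken
  state
}

#' Digestive water and sodium fluxes for one minute
#'
#' First-order transit kinetics: the stomach empties into the intestine
#' and exchanges water passively with the ECF; intestinal water is
#' absorbed into the ECF, carrying sodium passively, while intestinal
#' sodium is also absorbed actively. Stomach sodium travels with its
#' water at the gastric concentration.
#'
#' @param state an `hh_state`.
#' @param params an [hh_params()] object.
#' @return A list of class `hh_gut_fluxes` with per-minute fluxes (all
#'   >= 0): `stomach_to_intestine_w`, `stomach_to_ecf_w`,
#'   `intestine_to_ecf_w` (ml/min) and the corresponding sodium fluxes
#'   `stomach_to_intestine_na`, `stomach_to_ecf_na`, `intestine_to_ecf_na`
#'   (mmol/min).
#' @export
gut_fluxes <- function(state, params) {
  g <- params$gut
  sv <- state$stomach_v
  s_conc <- if (sv > 0) state$stomach_na / sv else 0
  f_si_w <- g$k_stomach_intestine * sv
  f_se_w <- g$k_stomach_ecf * sv
  iv <- state$intestine_v
  i_conc <- if (iv > 0) state$intestine_na / iv else 0
  f_ie_w <- g$k_intestine_ecf * iv
  na_active <- g$k_na_active * state$intestine_na
  fl <- list(
    stomach_to_intestine_w = f_si_w,
    stomach_to_ecf_w = f_se_w,
    intestine_to_ecf_w = f_ie_w,
    stomach_to_intestine_na = f_si_w * s_conc,
    stomach_to_ecf_na = f_se_w * s_conc,
    intestine_to_ecf_na = f_ie_w * i_conc + na_active
  )
  class(fl) <- "hh_gut_fluxes"
  fl
}

#' Advance the digestive compartments by one minute
#'
#' Applies [gut_fluxes()] to the stomach, intestine and ECF, conserving
#' water and sodium exactly, and releases the stomach-fullness lock once
#' the stomach volume falls below the comfort level.
#'
#' @inheritParams gut_fluxes
#' @return The updated state; the fluxes used are attached as attribute
#'   `"fluxes"`.
#' @export
gut_step <- function(state, params) {
  fl <- gut_fluxes(state, params)
  state$stomach_v <- state$stomach_v -
    (fl$stomach_to_intestine_w + fl$stomach_to_ecf_w)
  state$stomach_na <- state$stomach_na -
    (fl$stomach_to_intestine_na + fl$stomach_to_ecf_na)
  state$intestine_v <- state$intestine_v +
    fl$stomach_to_intestine_w - fl$intestine_to_ecf_w
  state$intestine_na <- state$intestine_na +
    fl$stomach_to_intestine_na - fl$intestine_to_ecf_na
  # guard against tiny negative residues from floating arithmetic
  state$stomach_v <- max(0, state$stomach_v)
  state$stomach_na <- max(0, state$stomach_na)
  state$intestine_v <- max(0, state$intestine_v)
  state$intestine_na <- max(0, state$intestine_na)
  state <- apply_fluxes(state,
                        fl$stomach_to_ecf_w + fl$intestine_to_ecf_w,
                        fl$stomach_to_ecf_na + fl$intestine_to_ecf_na)
  if (state$stomach_v < params$stomach_comfort_ml)
    state$drinking_locked <- FALSE
  attr(state, "fluxes") <- fl
  state
}
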