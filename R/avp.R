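#' Target AVP level from osmotic and volume state
#'
#' The main controller of the simulation: plasma AVP is a linear function
#' of the (corrected) extracellular sodium concentration and an
#' exponential function of the fractional extracellular volume deficit,
#' with a volume-dependent correction of the osmotic slope. With
#' `v = min(ecf_dv_frac, 0)` (volume excess does not suppress secretion
#' below the osmotic demand) and `n = na_conc / 1000` mol/L:
#'
#' `AVP = max(0, (0.91 - 11 v) * 200 * (n - 0.1375) + 1.3 * exp(-17 v))`
#'
#' @param na_conc extracellular sodium concentration, mmol/L.
#' @param ecf_dv_frac fractional deviation of the ECF volume from its
#'   initial value, `(ecf_v - ecf_v0) / ecf_v0`.
#' @return Target AVP, pg/ml (never negative).
#' @examples
#' avp_target(140, 0)      # 1.755
#' avp_target(137.5, 0)    # 1.3: the osmotic term vanishes
#' avp_target(140, -0.02)  # hypovolemia raises the target
#' @export
avp_target <- function(na_conc, ecf_dv_frac) {
  stopifnot(na_conc >= 0)
  v <- pmin(ecf_dv_frac, 0)
  n <- na_conc / 1000
  pmax(0, (0.91 - 11 * v) * (200 * (n - 0.1375)) + 1.3 * exp(-17 * v))
}

#' Clearance-limited AVP adjustment
#'
#' Secretion raises circulating AVP to its target instantaneously; decay
#' towards a lower target is limited by hepatic/renal clearance removing a
#' fixed fraction of circulating AVP per minute.
#'
#' @param current current AVP, pg/ml.
#' @param target target AVP from [avp_target()], pg/ml.
#' @param clearance_frac fraction cleared per minute (default 0.15).
#' @return The AVP level after one minute.
#' @examples
#' avp_update(10, 1.755)  # 8.5: decay limited to 15%/min
#' avp_update(1, 3)       # 3: secretion is instantaneous
#' @export
avp_update <- function(current, target, clearance_frac = 0.15) {
  stopifnot(current >= 0, target >= 0)
  if (target >= current) target else max(target, current * (1 - clearance_frac))
}

#' Circadian modulation factor on circulating AVP
#'
#' A pre-sleep reduction of circulating AVP: the level falls linearly at
#' 5\%/h from 02:00 to a nadir of -30\% at 08:00 (onset of the sleeping
#' period), then the modulation is progressively inactivated, linearly,
#' until 11:00. Outside this window the factor is 1.
#'
#' @param time_of_day minutes past midnight, in [0, 1440).
#' @param circ list with `start_min`, `nadir_min`, `restored_min` and
#'   `depth` (see [hh_params()]).
#' @return Multiplicative factor on the AVP level, in `[1 - depth, 1]`.
#' @examples
#' circadian_factor(120)  # 1 at 02:00
#' circadian_factor(480)  # 0.70 at 08:00
#' @export
circadian_factor <- function(time_of_day,
                             circ = list(start_min = 120, nadir_min = 480,
                                         restored_min = 660, depth = 0.30)) {
  if (any(time_of_day < 0 | time_of_day >= 1440))
    stop("time_of_day must lie in [0, 1440)")
  f <- rep(1, length(time_of_day))
  falling <- time_of_day >= circ$start_min & time_of_day < circ$nadir_min
  rising <- time_of_day >= circ$nadir_min & time_of_day < circ$restored_min
  f[falling] <- 1 - circ$depth * (time_of_day[falling] - circ$start_min) /
    (circ$nadir_min - circ$start_min)
  f[rising] <- (1 - circ$depth) + circ$depth *
    (time_of_day[rising] - circ$nadir_min) /
    (circ$restored_min - circ$nadir_min)
  f
}
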