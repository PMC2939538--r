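#' Build an empty (control) protocol
#'
#' A protocol is pure data: a duration plus a time-ordered list of
#' external events that the engine applies while stepping. Event kinds:
#' \describe{
#'   \item{`na_infusion`}{`total_mmol` of sodium added to the ECF at a
#'     constant rate over `duration_min` minutes (no water).}
#'   \item{`furosemide_injection`}{a diuretic injection; the kidney output
#'     is overridden by the furosemide time-course tables while they
#'     last.}
#'   \item{`water_access`}{`on = TRUE/FALSE`; gates all drinking from the
#'     event time onward.}
#'   \item{`water_na`}{`conc` (mmol/L) of the single available drinking
#'     water from the event time onward, or `NA` to restore the default
#'     two-bottle situation.}
#'   \item{`forced_drink`}{queue one additional drinking bout at the event
#'     time.}
#'   \item{`icf_exchange`}{`on = TRUE/FALSE`; when off, osmotic water
#'     exchange with the intracellular compartment is suspended.}
#' }
#'
#' @param days simulation length, whole days (>= 1).
#' @return An object of class `hh_protocol`.
#' @seealso [saline_challenge()], [furosemide_challenge()],
#'   [forced_drink_protocol()], [icf_block_protocol()]
#' @export
hh_protocol <- function(days = 1) {
  stopifnot(is.numeric(days), length(days) == 1L, days >= 1)
  p <- list(days = as.integer(days), events = list())
  class(p) <- "hh_protocol"
  p
}

#' Add an event to a protocol
#'
#' @param protocol an [hh_protocol()].
#' @param start_min event time, minutes since the start of the run
#'   (minute 0 = 08:00 of day 0).
#' @param kind event kind, see [hh_protocol()].
#' @param ... payload fields for the event.
#' @return The protocol with the event appended (events are kept
#'   time-ordered).
#' @export
add_event <- function(protocol, start_min, kind, ...) {
  stopifnot(inherits(protocol, "hh_protocol"),
            start_min >= 0, start_min < protocol$days * 1440)
  kinds <- c("na_infusion", "furosemide_injection", "water_access",
             "water_na", "forced_drink", "icf_exchange")
  kind <- match.arg(kind, kinds)
  ev <- c(list(start_min = start_min, kind = kind), list(...))
  if (kind == "na_infusion") {
    if (is.null(ev$duration_min) || ev$duration_min <= 0)
      stop("na_infusion requires a positive duration_min")
    if (is.null(ev$total_mmol) || ev$total_mmol <= 0)
      stop("na_infusion requires a positive total_mmol")
  }
  protocol$events <- append(protocol$events, list(ev))
  ord <- order(vapply(protocol$events, `[[`, numeric(1), "start_min"))
  protocol$events <- protocol$events[ord]
  protocol
}

#' Intracellular-dehydration (hypertonic saline) challenge
#'
#' A short jugular infusion of sodium without water: 1 mmol over 10
#' minutes, delivered during the sleeping period (default 10:00 of the
#' last day) on a control background.
#'
#' @param days total run length; the infusion falls on the last day.
#' @param start_min infusion start, minutes since the run start.
#' @param total_mmol sodium infused, mmol.
#' @param duration_min infusion duration, minutes.
#' @return An `hh_protocol`.
#' @export
saline_challenge <- function(days = 2,
                             start_min = (days - 1) * 1440 + 120,
                             total_mmol = 1, duration_min = 10) {
  add_event(hh_protocol(days), start_min, "na_infusion",
            total_mmol = total_mmol, duration_min = duration_min)
}

#' Extracellular-dehydration (furosemide) challenge
#'
#' Day 0 runs as its own control. On day 1 two furosemide injections are
#' given at 08:00 and 10:00; water (and the sodium source) is withheld
#' for the first 4 h; from 12:00 the animal has ad libitum access to a
#' single bottle whose sodium content stands in for the
#' sodium-deficient diet eaten over the remaining 20 h.
#'
#' @param days total run length (>= 2; day 0 is the control day).
#' @param water_na_conc sodium concentration, mmol/L, of the rehydration
#'   water from 12:00 of day 1 onward (tap water plus the dietary sodium
#'   compensation; calibrated default).
#' @return An `hh_protocol`.
#' @export
furosemide_challenge <- function(days = 2, water_na_conc = 11) {
  p <- hh_protocol(days)
  d1 <- 1440
  p <- add_event(p, d1, "water_access", on = FALSE)
  p <- add_event(p, d1, "furosemide_injection")
  p <- add_event(p, d1 + 120, "furosemide_injection")
  p <- add_event(p, d1 + 240, "water_access", on = TRUE)
  p <- add_event(p, d1 + 240, "water_na", conc = water_na_conc)
  p
}

#' Forced-drinking scenario
#'
#' A control run with one additional (forced) drinking bout queued at the
#' onset of the sleeping period, used to probe the sensitivity of the
#' sleeping AVP rise to early water intake.
#'
#' @param days run length.
#' @param at_min minute of the forced bout.
#' @param volume volume of the forced bout, ml (a full drinking episode).
#' @return An `hh_protocol`.
#' @export
forced_drink_protocol <- function(days = 2, at_min = (days - 1) * 1440,
                                  volume = 3) {
  add_event(hh_protocol(days), at_min, "forced_drink", volume = volume)
}

#' Blocked intracellular-exchange scenario
#'
#' A control run in which osmotic water transfer between the ICF and ECF
#' compartments is suspended, exposing the buffering role of the
#' intracellular compartment. By default the block covers the last day,
#' after a control warm-up day, so that a same-seed comparison against a
#' plain control run is free of initialisation transients.
#'
#' @param days run length.
#' @param start_min,end_min span (minutes) over which exchange is blocked.
#' @return An `hh_protocol`.
#' @export
icf_block_protocol <- function(days = 2, start_min = (days - 1) * 1440,
                               end_min = days * 1440) {
  p <- add_event(hh_protocol(days), start_min, "icf_exchange", on = FALSE)
  if (end_min < days * 1440)
    p <- add_event(p, end_min, "icf_exchange", on = TRUE)
  p
}

#' Furosemide urine output at a given time since injection
#'
#' Piecewise-linear evaluation of the calibrated furosemide time-course.
#' Beyond the table's horizon the diuretic has worn off and control
#' returns to the regular kidney model. When several injections overlap,
#' the engine takes the element-wise maximum flow.
#'
#' @param minutes_since_injection minutes since the injection (>= 0).
#' @param params an [hh_params()] object (supplies the tables).
#' @return A list with `flow_ul_100g` (ul/min/100 g), `na_conc` (mmol/L)
#'   and `active` (logical; `FALSE` beyond the horizon).
#' @export
furosemide_output <- function(minutes_since_injection, params) {
  stopifnot(minutes_since_injection >= 0)
  tab <- params$furosemide_flow_table
  horizon <- tab[nrow(tab), 1L]
  if (minutes_since_injection > horizon)
    return(list(flow_ul_100g = 0, na_conc = 0, active = FALSE))
  list(flow_ul_100g = eval_table(tab, minutes_since_injection),
       na_conc = eval_table(params$furosemide_na_table,
                            minutes_since_injection),
       active = TRUE)
}

# Expand a protocol into per-minute schedule vectors for the engine.
compile_protocol <- function(protocol, params) {
  n <- protocol$days * 1440L
  sched <- list(
    n = n,
    infusion_na = numeric(n),
    water_access = rep(TRUE, n),
    na_override = rep(NA_real_, n),
    forced = rep(FALSE, n),
    forced_volume = rep(NA_real_, n),
    icf_block = rep(FALSE, n),
    furo_inj = numeric(0)
  )
  access_state <- TRUE
  icf_state <- TRUE
  na_state <- NA_real_
  # toggle-style events apply from their start minute onward
  for (ev in protocol$events) {
    i0 <- as.integer(ev$start_min) + 1L
    idx <- i0:n
    switch(ev$kind,
      na_infusion = {
        span <- i0:min(n, i0 + ev$duration_min - 1L)
        sched$infusion_na[span] <- sched$infusion_na[span] +
          ev$total_mmol / ev$duration_min
      },
      furosemide_injection = {
        sched$furo_inj <- c(sched$furo_inj, ev$start_min)
      },
      water_access = {
        access_state <- isTRUE(ev$on)
        sched$water_access[idx] <- access_state
      },
      water_na = {
        na_state <- if (is.null(ev$conc)) NA_real_ else ev$conc
        sched$na_override[idx] <- na_state
      },
      forced_drink = {
        sched$forced[i0] <- TRUE
        if (!is.null(ev$volume)) sched$forced_volume[i0] <- ev$volume
      },
      icf_exchange = {
        icf_state <- isTRUE(ev$on)
        sched$icf_block[idx] <- !icf_state
      }
    )
  }
  sched
}

#' @export
print.hh_protocol <- function(x, ...) {
  cat(sprintf("hh_protocol: %d day(s), %d event(s)\n",
              x$days, length(x$events)))
  for (ev in x$events)
    cat(sprintf("  @%6d min  %s\n", ev$start_min, ev$kind))
  invisible(x)
}
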