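#' Advance the simulation by one minute
#'
#' The fixed within-minute update order is: (1) protocol sodium infusion;
#' (2) drinking decision and ingestion; (3) digestive transit; (4) the
#' constant insensible water balance; (5) kidney output (regular or
#' furosemide-overridden), computed from the sodium concentration and AVP
#' level of the previous minute; (6) osmotic water redistribution between
#' the compartments (unless blocked by the protocol); (7) AVP controller
#' update (target, clearance-limited adjustment, circadian modulation).
#'
#' @param state an `hh_state`.
#' @param params an [hh_params()] object.
#' @param infusion_na sodium infused this minute, mmol.
#' @param water_access logical; drinking allowed.
#' @param na_override drinking-water sodium override, mmol/L (or `NA`).
#' @param forced logical; queue a forced bout this minute.
#' @param forced_volume volume of a forced bout, ml (`NULL` = regular
#'   bout volume).
#' @param furo_override `NULL` or a furosemide kidney override (see
#'   [furosemide_output()]).
#' @param icf_block logical; suspend osmotic exchange this minute.
#' @param u uniform random draw for the drinking decision (see
#'   [decide_intake()]).
#' @return A list with `state` (advanced by one minute) and `row`, the
#'   per-minute observables (named numeric vector).
#' @export
hh_step <- function(state, params, infusion_na = 0, water_access = TRUE,
                    na_override = NA_real_, forced = FALSE,
                    forced_volume = NULL, furo_override = NULL,
                    icf_block = FALSE, u = stats::runif(1)) {
  tod <- (480L + state$t_min) %% 1440L
  na_prev <- ecf_na_conc(state)
  avp_prev <- state$avp

  # (1) protocol infusion (sodium only, no water)
  if (infusion_na != 0)
    state <- apply_fluxes(state, 0, infusion_na)

  # (2) drinking decision and ingestion
  dec <- decide_intake(state, params, tod, water_access = water_access,
                       na_override = na_override, forced = forced,
                       forced_volume = forced_volume, icf_block = icf_block,
                       u = u)
  state <- dec$state
  intake_ml <- 0
  intake_na <- 0
  if (dec$volume > 0) {
    state <- ingest(state, dec$volume, dec$na_conc, params)
    intake_ml <- attr(state, "ingested")
    intake_na <- intake_ml * dec$na_conc / 1000
  }

  # (3) digestive transit
  state <- gut_step(state, params)

  # (4) insensible water balance (net non-renal flux)
  state <- apply_fluxes(state, params$unregulated_balance_flux, 0)

  # (5) kidney
  renal <- kidney_step(state, params, na_conc_prev = na_prev,
                       avp_prev = avp_prev, override = furo_override)
  state <- apply_fluxes(state, -renal$urine_water, -renal$urine_na)

  # (6) osmotic redistribution
  if (!icf_block)
    state <- equilibrate_water(state, params)

  # (7) AVP controller
  ecf_v0 <- params$ecf_v_init_per100g * params$weight / 100
  dv <- (state$ecf_v - ecf_v0) / ecf_v0
  na_now <- ecf_na_conc(state)
  target <- avp_target(na_now, dv)
  state$avp_ctrl <- avp_update(state$avp_ctrl, target,
                               params$avp_clearance_frac_per_min)
  state$avp <- state$avp_ctrl * circadian_factor(tod, params$circadian_avp)

  state$t_min <- state$t_min + 1L
  row <- c(
    t_min = state$t_min - 1L, tod = tod,
    na_conc = na_now, ecf_v = state$ecf_v, icf_v = state$icf_v,
    avp = state$avp, avp_ctrl = state$avp_ctrl,
    urine_flow = renal$urine_water, urine_na = renal$urine_na,
    urine_na_conc = renal$urine_na_conc,
    ald = renal$ald_factor, anp = renal$anp_factor,
    intake_ml = intake_ml, intake_na = intake_na,
    intake_kind = switch(dec$kind, none = 0, need_induced = 1,
                         unregulated = 2),
    infusion_na = infusion_na,
    stomach_v = state$stomach_v, stomach_na = state$stomach_na,
    intestine_v = state$intestine_v, intestine_na = state$intestine_na,
    need_active = as.numeric(state$need_active),
    locked = as.numeric(state$drinking_locked),
    furo_active = as.numeric(!is.null(furo_override)),
    icf_blocked = as.numeric(icf_block)
  )
  list(state = state, row = row)
}

#' Run the simulator
#'
#' Steps the model at one-minute resolution for the duration of the
#' protocol, starting from [init_state()]. Given the same parameters,
#' protocol and seed the run is reproducible bit for bit.
#'
#' @param params an [hh_params()] object.
#' @param protocol an [hh_protocol()]; defaults to a control run of
#'   `days` days.
#' @param days run length when no protocol is supplied.
#' @param seed RNG seed for the stochastic drinking process.
#' @return An object of class `hh_series`: a data frame with one row per
#'   minute holding the state observables (volumes in ml, concentrations
#'   in mmol/L, AVP in pg/ml, fluxes in ml/min or mmol/min) plus the
#'   cumulative columns `cum_urine`, `cum_intake` (ml) and
#'   `cum_na_intake` (mmol). Attributes: `params`, `protocol`, `seed`.
#' @examples
#' series <- simulate_hh(hh_params(), days = 1, seed = 1)
#' nrow(series)  # 1440
#' @export
simulate_hh <- function(params = hh_params(), protocol = NULL, days = 1,
                        seed = 1) {
  if (is.null(protocol)) protocol <- hh_protocol(days)
  stopifnot(inherits(protocol, "hh_protocol"))
  set.seed(as.integer(seed))
  sched <- compile_protocol(protocol, params)
  n <- sched$n
  state <- init_state(params)
  # one uniform per minute, pre-drawn: runs with the same seed see the same
  # random stream whatever the protocol does (common random numbers)
  u_seq <- stats::runif(n)
  horizon <- params$furosemide_flow_table[nrow(params$furosemide_flow_table), 1L]
  rows <- matrix(NA_real_, nrow = n, ncol = 24L)
  for (i in seq_len(n)) {
    t_abs <- i - 1L
    furo <- NULL
    if (length(sched$furo_inj)) {
      since <- t_abs - sched$furo_inj
      act <- since >= 0 & since <= horizon
      if (any(act)) {
        outs <- lapply(since[act], furosemide_output, params = params)
        flows <- vapply(outs, `[[`, numeric(1), "flow_ul_100g")
        j <- which.max(flows)
        furo <- list(flow_ul_100g = flows[j], na_conc = outs[[j]]$na_conc)
      }
    }
    res <- hh_step(state, params,
                   infusion_na = sched$infusion_na[i],
                   water_access = sched$water_access[i],
                   na_override = sched$na_override[i],
                   forced = sched$forced[i],
                   forced_volume = sched$forced_volume[i],
                   furo_override = furo,
                   icf_block = sched$icf_block[i], u = u_seq[i])
    state <- res$state
    if (i == 1L) colnames(rows) <- names(res$row)
    rows[i, ] <- res$row
  }
  out <- as.data.frame(rows)
  out$cum_urine <- cumsum(out$urine_flow)
  out$cum_intake <- cumsum(out$intake_ml)
  out$cum_na_intake <- cumsum(out$intake_na)
  class(out) <- c("hh_series", "data.frame")
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol
  attr(out, "seed") <- seed
  out
}

#' Minute-of-day circadian profile
#'
#' Averages each observable at every minute of the day across the days of
#' the run, reducing inter-day fluctuation and exposing the circadian
#' trend (1440 mean and SD values per variable).
#'
#' @param series an `hh_series` spanning at least two full days.
#' @param vars observable columns to profile.
#' @return A data frame with `tod` (minutes past midnight) and, for each
#'   variable, `<var>_mean` and `<var>_sd` columns; attribute `days`.
#' @export
circadian_profile <- function(series,
                              vars = c("na_conc", "avp", "ecf_v", "icf_v",
                                       "urine_flow", "intake_ml")) {
  days <- nrow(series) / 1440
  if (days < 2 || days != round(days))
    stop("circadian_profile needs a whole number of days, at least 2")
  tod <- series$tod
  out <- data.frame(tod = 0:1439)
  for (v in vars) {
    m <- matrix(series[[v]][order(tod)], nrow = days)
    out[[paste0(v, "_mean")]] <- colMeans(m)
    out[[paste0(v, "_sd")]] <- apply(m, 2, stats::sd)
  }
  attr(out, "days") <- days
  out
}

#' Detect the restoration and maintenance phases
#'
#' The waking period splits into a restoration phase, starting at the
#' peak of the day-averaged AVP profile, and a maintenance phase, whose
#' onset is the first minute after the peak at which the mean AVP falls
#' to the upper bound of the 95\% confidence interval of the steady
#' pre-sleep AVP level (computed over the 02:00-08:00 window across
#' days).
#'
#' @param series an `hh_series` of at least two full days.
#' @return A list of class `hh_phases`: `restoration_onset` and
#'   `maintenance_onset` (minutes past midnight; the latter `NA` if the
#'   profile never crosses the threshold), `maintenance_threshold` and
#'   `ci` (the 95\% CI of the steady AVP level, pg/ml).
#' @export
detect_phases <- function(series) {
  prof <- circadian_profile(series, vars = "avp")
  days <- attr(prof, "days")
  avp_mean <- prof$avp_mean
  restoration <- prof$tod[which.max(avp_mean)]
  # steady pre-sleep window, 02:00-08:00: one mean per day, CI across days
  win <- series$tod >= 120 & series$tod < 480
  day_idx <- floor(series$t_min[win] / 1440)
  day_means <- tapply(series$avp[win], day_idx, mean)
  m <- mean(day_means)
  half <- 1.96 * stats::sd(day_means) / sqrt(length(day_means))
  threshold <- m + half
  # first crossing after the restoration onset, scanning cyclically
  ord <- ((restoration + seq_len(1440)) %% 1440) + 1L
  below <- avp_mean[ord] <= threshold
  maintenance <- if (any(below)) prof$tod[ord[which(below)[1L]]] else NA_real_
  out <- list(restoration_onset = restoration,
              maintenance_onset = maintenance,
              maintenance_threshold = threshold,
              ci = c(lower = m - half, upper = m + half))
  class(out) <- "hh_phases"
  out
}

#' @export
print.hh_phases <- function(x, ...) {
  fmt <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)
  cat("Circadian phases (minute-of-day AVP profile)\n")
  cat(sprintf("  restoration onset:  %s (AVP peak)\n",
              fmt(x$restoration_onset)))
  cat(sprintf("  maintenance onset:  %s (threshold %.2f pg/ml)\n",
              if (is.na(x$maintenance_onset)) "not reached"
              else fmt(x$maintenance_onset), x$maintenance_threshold))
  cat(sprintf("  steady AVP 95%% CI:  %.2f-%.2f pg/ml\n",
              x$ci["lower"], x$ci["upper"]))
  invisible(x)
}

# Minutes of day belonging to the maintenance phase: from the maintenance
# onset forward (cyclically) to 02:00, the start of the circadian AVP
# reduction; if the onset itself falls inside 02:00-08:00, the window runs
# to the sleep onset (08:00) instead.
maintenance_window <- function(phases) {
  on <- phases$maintenance_onset
  if (is.na(on)) return(integer(0))
  end <- if (on >= 120 && on < 480) 480 else 120
  span <- (on + 0:((end - on) %% 1440)) %% 1440
  span[-length(span)]
}

#' Summarise a simulation run
#'
#' Daily means and standard deviations of the six headline observables
#' (volumes per 100 g body weight where customary), circadian phase
#' detection, and sleeping- versus waking-period sub-statistics. The
#' sleeping period is 08:00-20:00, the waking period 20:00-08:00.
#'
#' @param series an `hh_series` covering at least one full day.
#' @param params the [hh_params()] used for the run (defaults to the
#'   series attribute).
#' @return An object of class `hh_summary`: `daily` (per-day values),
#'   `mean`/`sd` (across days), `phases` (when the run spans >= 2 days),
#'   `maintenance_avp` (mean and sd across days of the maintenance-phase
#'   AVP), and `periods` (sleeping/waking sub-means).
#' @export
summarize_hh <- function(series, params = attr(series, "params")) {
  n <- nrow(series)
  days <- n / 1440
  if (days < 1 || days != round(days))
    stop("summarize_hh needs a whole number of days")
  scale <- params$weight / 100
  day <- floor(series$t_min / 1440)
  per_day <- function(x, f) as.numeric(tapply(x, day, f))
  daily <- data.frame(
    day = 0:(days - 1),
    ecf_na_conc = per_day(series$na_conc, mean),
    ecf_v_per100g = per_day(series$ecf_v, mean) / scale,
    icf_v_per100g = per_day(series$icf_v, mean) / scale,
    avp = per_day(series$avp, mean),
    urine_ml_per100g = per_day(series$urine_flow, sum) / scale,
    intake_ml_per100g = per_day(series$intake_ml, sum) / scale,
    na_intake_mmol_per100g = per_day(series$intake_na, sum) / scale
  )
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  stats_cols <- setdiff(names(daily), "day")
  out <- list(
    daily = daily,
    mean = vapply(daily[stats_cols], mean, numeric(1)),
    sd = vapply(daily[stats_cols], sd0, numeric(1)),
    days = days
  )
  if (days >= 2) {
    phases <- detect_phases(series)
    out$phases <- phases
    win <- maintenance_window(phases)
    if (length(win)) {
      sel <- series$tod %in% win
      dm <- tapply(series$avp[sel], day[sel], mean)
      out$maintenance_avp <- c(mean = mean(dm), sd = sd0(as.numeric(dm)))
    }
  }
  sleeping <- series$tod >= 480 & series$tod < 1200
  out$periods <- rbind(
    sleeping = c(avp = mean(series$avp[sleeping]),
                 na_conc = mean(series$na_conc[sleeping]),
                 urine_flow = mean(series$urine_flow[sleeping]),
                 urine_na_conc = mean(series$urine_na_conc[sleeping]),
                 intake_ml_per_day = sum(series$intake_ml[sleeping]) / days),
    waking = c(avp = mean(series$avp[!sleeping]),
               na_conc = mean(series$na_conc[!sleeping]),
               urine_flow = mean(series$urine_flow[!sleeping]),
               urine_na_conc = mean(series$urine_na_conc[!sleeping]),
               intake_ml_per_day = sum(series$intake_ml[!sleeping]) / days)
  )
  class(out) <- "hh_summary"
  out
}

#' @export
print.hh_summary <- function(x, ...) {
  cat(sprintf("Simulation summary over %d day(s)\n", x$days))
  lab <- c(ecf_na_conc = "ECF [Na+] (mmol/L)",
           ecf_v_per100g = "ECF volume (ml/100 g)",
           icf_v_per100g = "ICF volume (ml/100 g)",
           avp = "AVP, daily mean (pg/ml)",
           urine_ml_per100g = "urine volume (ml/100 g/day)",
           intake_ml_per100g = "water intake (ml/100 g/day)",
           na_intake_mmol_per100g = "Na+ intake (mmol/100 g/day)")
  for (nm in names(lab))
    cat(sprintf("  %-28s %6.2f +/- %.2f\n", lab[nm], x$mean[nm], x$sd[nm]))
  if (!is.null(x$maintenance_avp))
    cat(sprintf("  %-28s %6.2f +/- %.2f\n",
                "AVP, maintenance (pg/ml)",
                x$maintenance_avp["mean"], x$maintenance_avp["sd"]))
  if (!is.null(x$phases)) print(x$phases)
  invisible(x)
}

#' Sub-period statistics of a run
#'
#' Means and cumulative totals over an arbitrary span of minutes; handy
#' for challenge protocols reporting, e.g., the first 4 h of a treatment
#' day.
#'
#' @param series an `hh_series`.
#' @param start_min,end_min span, minutes since the run start
#'   (`start_min` inclusive, `end_min` exclusive).
#' @param params the [hh_params()] used for the run.
#' @return A named numeric vector: mean ECF sodium, AVP, volumes per
#'   100 g, final ECF sodium, cumulative urine, urine sodium, intake and
#'   sodium intake per 100 g over the span, and the maximal AVP.
#' @export
period_stats <- function(series, start_min, end_min,
                         params = attr(series, "params")) {
  sel <- series$t_min >= start_min & series$t_min < end_min
  if (!any(sel)) stop("empty period")
  scale <- params$weight / 100
  s <- series[sel, ]
  c(mean_na_conc = mean(s$na_conc),
    mean_avp = mean(s$avp),
    max_avp = max(s$avp),
    mean_ecf_v_per100g = mean(s$ecf_v) / scale,
    mean_icf_v_per100g = mean(s$icf_v) / scale,
    end_na_conc = s$na_conc[nrow(s)],
    urine_ml_per100g = sum(s$urine_flow) / scale,
    urine_na_mmol_per100g = sum(s$urine_na) / scale,
    intake_ml_per100g = sum(s$intake_ml) / scale,
    na_intake_mmol_per100g = sum(s$intake_na) / scale)
}
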