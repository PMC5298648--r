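# Gait event detection: a per-foot two-state machine on the heel and toe
# point speeds, with thresholds proportional to the trial's mean pelvis
# speed, plus a force-plate reference detector for evaluation.

#' Velocity threshold of a trial
#'
#' The norm of the time-averaged pelvis velocity vector (not the mean of
#' norms): lateral and vertical oscillations cancel, leaving the mean
#' progression speed.
#'
#' @param pelvis_velocity n x 3 pelvis velocity (m/s).
#' @return Scalar threshold speed `v_th` (m/s).
#' @export
compute_vth <- function(pelvis_velocity) {
  if (NROW(pelvis_velocity) == 0) stopf("compute_vth: empty series")
  sqrt(sum(colMeans(as.matrix(pelvis_velocity))^2))
}

#' Event detection configuration
#'
#' @param heel_multiplier heel-strike threshold as a multiple of `v_th`
#'   (default 0.6).
#' @param toe_multiplier toe-off threshold as a multiple of `v_th`
#'   (default 1.9).
#' @param min_gap_s minimum time between successive events on one foot,
#'   suppressing chatter near the threshold (default 0.05 s).
#' @return List of class `threshold_config`.
#' @export
threshold_config <- function(heel_multiplier = 0.6, toe_multiplier = 1.9,
                             min_gap_s = 0.05) {
  if (heel_multiplier <= 0 || toe_multiplier <= 0)
    stopf("threshold_config: multipliers must be positive")
  structure(list(heel_multiplier = heel_multiplier,
                 toe_multiplier = toe_multiplier,
                 min_gap_s = min_gap_s),
            class = "threshold_config")
}

#' Detect one foot's events from heel and toe speeds
#' @noRd
detect_events_one_foot <- function(time, heel_speed, toe_speed, vth, config) {
  th_hs <- config$heel_multiplier * vth
  th_to <- config$toe_multiplier * vth
  state <- if (heel_speed[1] < th_hs) "stance" else "swing"
  events <- list()
  last_t <- -Inf
  for (i in seq_along(time)) {
    if (time[i] - last_t < config$min_gap_s) next
    if (state == "swing" && heel_speed[i] < th_hs) {
      events[[length(events) + 1L]] <- list(event = "heel_strike",
                                            time = time[i], index = i)
      state <- "stance"; last_t <- time[i]
    } else if (state == "stance" && toe_speed[i] > th_to) {
      events[[length(events) + 1L]] <- list(event = "toe_off",
                                            time = time[i], index = i)
      state <- "swing"; last_t <- time[i]
    }
  }
  list(events = events, initial_state = if (heel_speed[1] < th_hs) "stance" else "swing")
}

#' Detect heel-strike and toe-off events from point speeds
#'
#' Per-foot two-state machine: in swing, a heel strike is declared at the
#' first sample where the heel speed falls below `heel_multiplier * v_th`;
#' in stance, a toe-off at the first sample where the toe speed rises above
#' `toe_multiplier * v_th`. The initial state of each foot is inferred from
#' its first heel-speed sample. Event times are whole sample times (no
#' sub-sample interpolation).
#'
#' @param time time grid (s).
#' @param heel_speed_l,heel_speed_r,toe_speed_l,toe_speed_r speed norms
#'   (m/s) of the heel and toe points of each foot.
#' @param vth trial velocity threshold from [compute_vth()], > 0.
#' @param config a [threshold_config()].
#' @return A `gait_events` data.frame with columns `foot` ("left"/"right"),
#'   `event` ("heel_strike"/"toe_off"), `time`, `index`; attributes `vth`
#'   and `initial_state` (named character). Empty with a warning when no
#'   events are found.
#' @export
detect_events <- function(time, heel_speed_l, toe_speed_l,
                          heel_speed_r, toe_speed_r, vth,
                          config = threshold_config()) {
  if (vth <= 0) stopf("detect_events: vth must be positive")
  L <- detect_events_one_foot(time, heel_speed_l, toe_speed_l, vth, config)
  R <- detect_events_one_foot(time, heel_speed_r, toe_speed_r, vth, config)
  rows <- c(lapply(L$events, function(e) data.frame(foot = "left", event = e$event,
                                                    time = e$time, index = e$index)),
            lapply(R$events, function(e) data.frame(foot = "right", event = e$event,
                                                    time = e$time, index = e$index)))
  if (!length(rows)) {
    warnf("detect_events: no gait events found")
    ev <- data.frame(foot = character(0), event = character(0),
                     time = numeric(0), index = integer(0))
  } else {
    ev <- do.call(rbind, rows)
    ev <- ev[order(ev$time, ev$foot), ]
    rownames(ev) <- NULL
  }
  structure(ev, class = c("gait_events", "data.frame"),
            vth = vth,
            initial_state = c(left = L$initial_state, right = R$initial_state))
}

#' Reference gait events from force-plate vertical force
#'
#' Heel strike at the upward crossing of the force threshold, toe-off at
#' the downward crossing (5 N by default).
#'
#' @param time time grid (s).
#' @param fz_l,fz_r vertical force under each foot (N).
#' @param threshold_N crossing threshold (default 5 N).
#' @return A `gait_events` data.frame as in [detect_events()].
#' @export
detect_events_forceplate <- function(time, fz_l, fz_r, threshold_N = 5) {
  one <- function(fz, foot) {
    on <- !is.na(fz) & fz > threshold_N
    off <- !is.na(fz) & fz <= threshold_N
    rows <- list()
    for (i in seq_along(on)[-1]) {
      if (on[i] && off[i - 1])
        rows[[length(rows) + 1L]] <- data.frame(foot = foot, event = "heel_strike",
                                                time = time[i], index = i)
      if (off[i] && on[i - 1])
        rows[[length(rows) + 1L]] <- data.frame(foot = foot, event = "toe_off",
                                                time = time[i], index = i)
    }
    rows
  }
  rows <- c(one(fz_l, "left"), one(fz_r, "right"))
  ev <- if (length(rows)) {
    x <- do.call(rbind, rows); x <- x[order(x$time, x$foot), ]; rownames(x) <- NULL; x
  } else {
    data.frame(foot = character(0), event = character(0),
               time = numeric(0), index = integer(0))
  }
  init <- c(left = if (fz_l[1] > threshold_N) "stance" else "swing",
            right = if (fz_r[1] > threshold_N) "stance" else "swing")
  structure(ev, class = c("gait_events", "data.frame"), initial_state = init)
}

#' Per-foot stance intervals implied by an event table
#'
#' Reconstructs stance intervals (sample-index ranges) for one foot from its
#' alternating heel-strike/toe-off events and the inferred initial state.
#'
#' @param events a `gait_events` table.
#' @param foot `"left"` or `"right"`.
#' @param n_samples length of the underlying time grid.
#' @return Data.frame with columns `start`, `end` (sample indices,
#'   inclusive; the foot is on the ground on `[start, end - 1]` and airborne
#'   from `end`).
#' @export
stance_intervals <- function(events, foot, n_samples) {
  ev <- events[events$foot == foot, , drop = FALSE]
  init <- attr(events, "initial_state")[[foot]] %||% "swing"
  for (i in seq_len(nrow(ev))[-1]) {
    if (ev$event[i] == ev$event[i - 1])
      stopf("stance_intervals: events do not alternate for %s foot", foot)
  }
  starts <- integer(0); ends <- integer(0)
  open <- if (init == "stance") 1L else NA_integer_
  for (i in seq_len(nrow(ev))) {
    if (ev$event[i] == "heel_strike") {
      if (!is.na(open)) stopf("stance_intervals: heel strike during stance (%s)", foot)
      open <- ev$index[i]
    } else {
      if (is.na(open)) stopf("stance_intervals: toe-off during swing (%s)", foot)
      starts <- c(starts, open); ends <- c(ends, ev$index[i]); open <- NA_integer_
    }
  }
  if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, n_samples + 1L) }
  data.frame(start = starts, end = ends)
}

#' Label each sample with its gait phase
#'
#' Phases: `"ss_left"` / `"ss_right"` (single support), `"ds_lead_left"` /
#' `"ds_lead_right"` (double support, named after the leading foot — the
#' one that struck most recently; the other foot is trailing), `"none"`
#' when neither foot is grounded. The first double stance of an ipsilateral
#' foot is the one it leads; its second double stance is the one it trails.
#'
#' @param events a `gait_events` table.
#' @param time the time grid the events refer to.
#' @return Character vector of phase labels, one per sample, with the
#'   per-foot stance masks as attributes `stance_left` / `stance_right`.
#' @export
label_phases <- function(events, time) {
  n <- length(time)
  mask <- function(foot) {
    iv <- stance_intervals(events, foot, n)
    m <- logical(n)
    for (i in seq_len(nrow(iv))) {
      lo <- iv$start[i]; hi <- min(n, iv$end[i] - 1L)
      if (hi >= lo) m[lo:hi] <- TRUE
    }
    m
  }
  sl <- mask("left"); sr <- mask("right")
  # leading foot during double support: the most recent heel strike
  hs <- events[events$event == "heel_strike", , drop = FALSE]
  last_hs_foot <- character(n)
  cur <- NA_character_; j <- 1L
  for (i in seq_len(n)) {
    while (j <= nrow(hs) && hs$index[j] <= i) { cur <- hs$foot[j]; j <- j + 1L }
    last_hs_foot[i] <- cur
  }
  lab <- rep("none", n)
  lab[sl & !sr] <- "ss_left"
  lab[sr & !sl] <- "ss_right"
  both <- sl & sr
  lab[both & (last_hs_foot %in% "left")] <- "ds_lead_left"
  lab[both & (last_hs_foot %in% "right")] <- "ds_lead_right"
  lab[both & is.na(last_hs_foot)] <- "ds_lead_right"  # before any HS: arbitrary
  structure(lab, stance_left = sl, stance_right = sr)
}

#' Gait cycles of one foot
#'
#' A gait cycle spans two consecutive heel strikes of the same foot.
#'
#' @param events a `gait_events` table.
#' @param foot `"left"` or `"right"`.
#' @return Data.frame with columns `start_time`, `end_time`, `start_index`,
#'   `end_index`, one row per complete cycle.
#' @export
gait_cycles <- function(events, foot) {
  hs <- events[events$foot == foot & events$event == "heel_strike", , drop = FALSE]
  if (nrow(hs) < 2)
    return(data.frame(start_time = numeric(0), end_time = numeric(0),
                      start_index = integer(0), end_index = integer(0)))
  data.frame(start_time = hs$time[-nrow(hs)], end_time = hs$time[-1],
             start_index = hs$index[-nrow(hs)], end_index = hs$index[-1])
}
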