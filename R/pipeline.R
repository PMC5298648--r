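# Full prediction pipeline: filtering -> Newton-Euler -> event detection ->
# double-support distribution -> per-foot outputs, plus the evaluation
# driver and the two sensitivity sweeps.

#' Pipeline configuration
#'
#' All defaults are the reference operating point of the method: 6 Hz
#' second-order zero-phase Butterworth filtering, heel/toe threshold
#' multipliers 0.6 and 1.9, 5 N vertical-force threshold, 101-point gait
#' cycle grid, g = 9.81 m/s^2.
#'
#' @param cutoff_hz low-pass cut-off (Hz).
#' @param filter_order Butterworth order of a single pass.
#' @param heel_multiplier,toe_multiplier event-detection thresholds as
#'   multiples of the trial velocity threshold.
#' @param fz_threshold_N vertical-force threshold for COP validity and
#'   force-plate event detection.
#' @param sta an [sta_function()] (default [sta_default()]).
#' @param min_gap_s minimum inter-event gap per foot (s).
#' @param min_displacement_m minimum pelvis displacement for the walking
#'   frame.
#' @param n_points gait-cycle resampling grid size.
#' @param g gravitational acceleration magnitude (m/s^2).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cutoff_hz = 6, filter_order = 2,
                            heel_multiplier = 0.6, toe_multiplier = 1.9,
                            fz_threshold_N = 5, sta = sta_default(),
                            min_gap_s = 0.05, min_displacement_m = 0.5,
                            n_points = 101, g = 9.81) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Point velocities, computed from positions where absent
#' @noRd
point_velocity <- function(kin, name) {
  p <- kin$points[[name]]
  if (is.null(p)) stopf("run_predict: kinematics lack tracked point '%s'", name)
  p$vel %||% central_diff(p$pos, 1 / kin$fs)
}

#' Predict per-foot ground reaction wrenches from kinematics
#'
#' Runs the full pipeline: angular-acceleration differentiation, zero-phase
#' low-pass filtering of the dynamic channels, Newton-Euler total external
#' wrench, rotation into the walking frame, heel/toe threshold gait event
#' detection, double-support distribution under the configured STA curves,
#' and per-foot centre of pressure and frictional torque.
#'
#' @param kin a [segment_kinematics()] with the 16 model segments and
#'   tracked points `heel_l`, `toe_l`, `heel_r`, `toe_r`.
#' @param body the matching [body_model()].
#' @param config a [pipeline_config()].
#' @param filter apply the low-pass filter (disable for noise-free
#'   analytic inputs).
#' @return List of class `grfm_prediction` with elements `total`, `left`,
#'   `right` ([wrench_series()] in the walking frame), `cop_left`,
#'   `cop_right`, `torque_left`, `torque_right`, `events`, `phase`, `vth`,
#'   `heading_rad`, `config`.
#' @export
run_predict <- function(kin, body, config = pipeline_config(), filter = TRUE) {
  kin <- differentiate_angular_velocity(kin)
  pelvis_vel <- central_diff(kin$segments$pelvis$pos, 1 / kin$fs)
  contact_points <- c("heel_l", "toe_l", "heel_r", "toe_r")
  has_points <- all(contact_points %in% names(kin$points))
  speeds <- if (has_points)
    lapply(stats::setNames(contact_points, contact_points),
           function(p) row_norms(point_velocity(kin, p)))
  if (filter) {
    kin <- filter_kinematics(kin, config$cutoff_hz, config$filter_order)
    pelvis_vel <- lowpass_filter(pelvis_vel, config$cutoff_hz, kin$fs,
                                 config$filter_order)
    if (has_points)
      speeds <- lapply(speeds, lowpass_filter, cutoff_hz = config$cutoff_hz,
                       fs = kin$fs, order = config$filter_order)
  }
  vth <- compute_vth(pelvis_vel)

  wf <- tryCatch(walking_frame(kin$segments$pelvis$pos, config$min_displacement_m),
                 error = function(e) NULL)
  if (is.null(wf)) {
    warnf("run_predict: walking direction undefined (stationary trial?); keeping the global frame")
    wf <- list(yaw_rotation = diag(3), heading_rad = 0)
  }
  total_g <- total_external_moment(body, kin, ref_point = c(0, 0, 0))
  total_w <- rotate_wrench(total_g, wf$yaw_rotation, frame = "walking")

  out <- list(total = total_w, left = NULL, right = NULL,
              cop_left = NULL, cop_right = NULL,
              torque_left = NULL, torque_right = NULL,
              events = NULL, phase = NULL, vth = vth,
              heading_rad = wf$heading_rad, config = config)
  if (!has_points || vth <= 0) {
    warnf("run_predict: no heel/toe points or zero threshold speed; returning the total wrench only")
    return(structure(out, class = "grfm_prediction"))
  }

  events <- detect_events(kin$time, speeds$heel_l, speeds$toe_l,
                          speeds$heel_r, speeds$toe_r, vth,
                          threshold_config(config$heel_multiplier,
                                           config$toe_multiplier,
                                           config$min_gap_s))
  ankle <- function(foot) {
    p <- rotate_rows(kin$segments[[foot]]$pos, wf$yaw_rotation)
    cbind(p[, 1:2], 0)
  }
  dist <- distribute_wrench(total_w, events, config$sta,
                            ankle("foot_l"), ankle("foot_r"))
  cop_l <- compute_cop(dist$left, config$fz_threshold_N)
  cop_r <- compute_cop(dist$right, config$fz_threshold_N)
  out$left <- dist$left; out$right <- dist$right
  out$cop_left <- cop_l; out$cop_right <- cop_r
  out$torque_left <- compute_frictional_torque(dist$left, cop_l)
  out$torque_right <- compute_frictional_torque(dist$right, cop_r)
  out$events <- events; out$phase <- dist$phase
  structure(out, class = "grfm_prediction")
}

#' @export
print.grfm_prediction <- function(x, ...) {
  cat(sprintf("<grfm_prediction> %d samples, vth %.3f m/s, %d events\n",
              length(x$total$time), x$vth, nrow(x$events)))
  invisible(x)
}

#' Sub-phase label of each cycle sample relative to one foot
#' @noRd
cycle_subphases <- function(events, foot, time, i0, i1) {
  contra <- if (foot == "left") "right" else "left"
  lab <- rep(NA_character_, i1 - i0 + 1)
  cev <- events[events$foot == contra, ]
  to_c <- cev$index[cev$event == "toe_off" & cev$index > i0 & cev$index <= i1][1]
  hs_c <- cev$index[cev$event == "heel_strike" & cev$index > i0 & cev$index <= i1][1]
  iev <- events[events$foot == foot, ]
  to_i <- iev$index[iev$event == "toe_off" & iev$index > i0 & iev$index <= i1][1]
  rel <- function(i) i - i0 + 1
  if (!is.na(to_c)) lab[rel(i0):(rel(to_c) - 1)] <- "DS1"
  if (!is.na(to_c) && !is.na(hs_c)) lab[rel(to_c):(rel(hs_c) - 1)] <- "SS"
  if (!is.na(hs_c) && !is.na(to_i)) lab[rel(hs_c):(rel(to_i) - 1)] <- "DS2"
  lab
}

#' Evaluate predicted against reference per-foot wrenches
#'
#' Gait cycles are taken between consecutive ipsilateral heel strikes of
#' the reference events (detected with the vertical-force threshold).
#' Both wrench sets are normalized to body weight (forces) and body weight
#' times height (moments), resampled to the percent-of-cycle grid, and
#' compared per component: Pearson rho with its category, RMSE, relative
#' RMSE, and Sprague-Geers magnitude/phase, computed per cycle and
#' averaged. Sub-phase (DS1/SS/DS2) metrics and the stance-phase peak table
#' are included. Cycles containing non-finite reference samples are
#' excluded and counted.
#'
#' @param pred a [run_predict()] result.
#' @param ref_left,ref_right reference [wrench_series()] (walking frame,
#'   moments about the respective ankle projections).
#' @param body the [body_model()] (for the normalisation constants).
#' @param config a [pipeline_config()].
#' @return List of class `metric_report`: `per_component` (averaged over
#'   cycles and feet), `subphases`, `peaks`, `n_cycles`, `n_excluded`.
#' @export
run_evaluate <- function(pred, ref_left, ref_right, body,
                         config = pipeline_config()) {
  time <- pred$total$time
  ref_events <- detect_events_forceplate(time, ref_left$force[, 3],
                                         ref_right$force[, 3],
                                         config$fz_threshold_N)
  bw <- body$total_mass * config$g
  bwh <- bw * body$height
  norm6 <- function(w) cbind(w$force / bw, w$moment / bwh)
  comp_names <- c("F_anterior", "F_lateral", "F_vertical",
                  "M_frontal", "M_sagittal", "M_transverse")

  per_cycle <- list(); sub_rows <- list()
  stance_pred <- list(); stance_meas <- list()
  n_excluded <- 0L; n_cycles <- 0L
  for (foot in c("left", "right")) {
    p6 <- norm6(if (foot == "left") pred$left else pred$right)
    m6 <- norm6(if (foot == "left") ref_left else ref_right)
    cyc <- gait_cycles(ref_events, foot)
    iev <- ref_events[ref_events$foot == foot, ]
    for (ci in seq_len(nrow(cyc))) {
      i0 <- cyc$start_index[ci]; i1 <- cyc$end_index[ci]
      if (!all(is.finite(m6[i0:i1, ])) || !all(is.finite(p6[i0:i1, ]))) {
        n_excluded <- n_excluded + 1L
        next
      }
      n_cycles <- n_cycles + 1L
      pc <- time_normalize(p6[i0:i1, ], time[i0:i1], time[i0], time[i1],
                           config$n_points)
      mc <- time_normalize(m6[i0:i1, ], time[i0:i1], time[i0], time[i1],
                           config$n_points)
      per_cycle[[length(per_cycle) + 1L]] <- do.call(rbind, lapply(1:6, function(j)
        cbind(component = comp_names[j], curve_metrics(pc[, j], mc[, j]))))
      sub <- cycle_subphases(ref_events, foot, time, i0, i1)
      for (j in 1:6) {
        sm <- suppressWarnings(
          subphase_metrics(p6[i0:i1, j], m6[i0:i1, j], sub))
        if (nrow(sm)) {
          sm$component <- comp_names[j]
          sub_rows[[length(sub_rows) + 1L]] <- sm
        }
      }
      to_i <- iev$index[iev$event == "toe_off" & iev$index > i0 & iev$index <= i1][1]
      if (!is.na(to_i)) {
        # mirror left-foot curves onto the right side (flip the lateral
        # force and frontal/transverse moments) before averaging feet
        mir <- if (foot == "left") rep(c(1, -1, 1, -1, 1, -1) == 1, 1) else rep(TRUE, 6)
        sgn <- ifelse(mir, 1, -1)
        stance_pred[[length(stance_pred) + 1L]] <- sweep(
          time_normalize(p6[i0:to_i, ], time[i0:to_i], time[i0], time[to_i], 100),
          2, sgn, "*")
        stance_meas[[length(stance_meas) + 1L]] <- sweep(
          time_normalize(m6[i0:to_i, ], time[i0:to_i], time[i0], time[to_i], 100),
          2, sgn, "*")
      }
    }
  }
  if (!n_cycles) stopf("run_evaluate: no overlapping complete gait cycles")

  all_pc <- do.call(rbind, per_cycle)
  agg <- do.call(rbind, lapply(split(all_pc, all_pc$component), function(d)
    data.frame(component = d$component[1],
               rho = mean(d$rho), rho_sd = stats::sd(d$rho),
               category = correlation_category(mean(d$rho)),
               rmse = mean(d$rmse), rrmse_percent = mean(d$rrmse_percent),
               M_percent = mean(d$M_percent), P_percent = mean(d$P_percent))))
  agg <- agg[match(comp_names, agg$component), ]
  rownames(agg) <- NULL

  subs <- if (length(sub_rows)) {
    allsub <- do.call(rbind, sub_rows)
    out <- do.call(rbind, lapply(split(allsub, list(allsub$component, allsub$phase)),
      function(d) if (!nrow(d)) NULL else
        data.frame(component = d$component[1], phase = d$phase[1],
                   rho = mean(d$rho), rmse = mean(d$rmse),
                   rrmse_percent = mean(d$rrmse_percent))))
    rownames(out) <- NULL
    out
  } else NULL

  peaks <- if (length(stance_pred)) {
    peak_analysis(Reduce(`+`, stance_pred) / length(stance_pred),
                  Reduce(`+`, stance_meas) / length(stance_meas))
  } else NULL

  structure(list(per_component = agg, subphases = subs, peaks = peaks,
                 n_cycles = n_cycles, n_excluded = n_excluded),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d cycles (%d excluded)\n", x$n_cycles, x$n_excluded))
  print(x$per_component, digits = 3)
  invisible(x)
}

#' Sensitivity sweeps over the filter cut-off or the event thresholds
#'
#' `kind = "cutoff"`: re-runs the prediction at each cut-off frequency and
#' reports the percent change in per-component RMSE (against the trial's
#' ground truth) relative to the baseline cut-off, plus the force and
#' moment vector norms. The baseline row is 0 by definition.
#' `kind = "threshold"`: scales both threshold multipliers by each grid
#' factor and reports the mean absolute heel-strike and toe-off timing
#' error (ms) against the trial's ground-truth events.
#'
#' @param kind `"cutoff"` or `"threshold"`.
#' @param grid numeric grid: cut-off frequencies in Hz, or multiplier scale
#'   factors (e.g. `c(0.9, 1, 1.1)`).
#' @param trial a [generate_trial()] result (provides input and truth).
#' @param config baseline [pipeline_config()].
#' @return Data.frame, one row per grid point.
#' @export
run_sweep <- function(kind = c("cutoff", "threshold"), grid, trial,
                      config = pipeline_config()) {
  kind <- match.arg(kind)
  if (kind == "cutoff") {
    rmse6 <- function(cutoff) {
      cfg <- config; cfg$cutoff_hz <- cutoff
      pred <- run_predict(trial$kinematics, trial$body, cfg)
      vapply(1:3, function(j) {
        sqrt(mean((pred$left$force[, j] - trial$truth$left$force[, j])^2 +
                  (pred$right$force[, j] - trial$truth$right$force[, j])^2))
      }, numeric(1)) -> f
      vapply(1:3, function(j) {
        sqrt(mean((pred$left$moment[, j] - trial$truth$left$moment[, j])^2 +
                  (pred$right$moment[, j] - trial$truth$right$moment[, j])^2))
      }, numeric(1)) -> m
      c(f, norm_F = sqrt(sum(f^2)), m, norm_M = sqrt(sum(m^2)))
    }
    base <- rmse6(config$cutoff_hz)
    rows <- t(vapply(grid, function(fc) 100 * (rmse6(fc) - base) / base,
                     numeric(8)))
    out <- data.frame(cutoff_hz = grid, rows)
    names(out)[-1] <- c("anterior", "lateral", "vertical", "norm_GRF",
                        "frontal", "sagittal", "transverse", "norm_GRM")
    out
  } else {
    event_err <- function(scale) {
      cfg <- config
      cfg$heel_multiplier <- config$heel_multiplier * scale
      cfg$toe_multiplier <- config$toe_multiplier * scale
      pred <- run_predict(trial$kinematics, trial$body, cfg)
      err <- function(type) {
        e1 <- pred$events[pred$events$event == type, ]
        e0 <- trial$events[trial$events$event == type, ]
        errs <- unlist(lapply(c("left", "right"), function(ft) {
          t1 <- e1$time[e1$foot == ft]; t0 <- e0$time[e0$foot == ft]
          vapply(t0, function(tt) {
            if (!length(t1)) return(NA_real_)
            min(abs(t1 - tt))
          }, numeric(1))
        }))
        mean(errs, na.rm = TRUE) * 1000
      }
      c(heel_strike_ms = err("heel_strike"), toe_off_ms = err("toe_off"))
    }
    rows <- t(vapply(grid, event_err, numeric(2)))
    data.frame(scale = grid, rows)
  }
}
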