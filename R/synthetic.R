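# Synthetic walking trials with exactly known ground truth. Segment motion
# is built from analytic (C-infinity) curves so every derivative is exact:
# a base trajectory whose second derivative reproduces a prescribed total
# external force through the Newton equation run in reverse, plus antiphase
# limb excursions whose mass-weighted sum is identically zero. Heel and toe
# point speeds are piecewise raised-cosine profiles that cross the
# detection thresholds midway between two samples, so the first sample
# beyond each crossing -- the detected event -- is exactly the prescribed
# event sample. Per-foot ground truth applies the same phase table and STA
# curves the predictor uses, coded independently here.

#' Specification of a synthetic walking trial
#'
#' Defaults emulate barefoot walking at self-selected normal speed:
#' 1.28 m/s, 1.2 s strides with 12.5% double-support fraction, sampled at
#' 240 Hz, for a 77.34 kg, 1.81 m subject. The total vertical force
#' oscillates around body weight at step frequency (amplitude
#' `vertical_amp` BW, giving the familiar two peaks per stride), with
#' smaller anterior and lateral shear oscillations.
#'
#' @param n_strides number of full strides (default 4).
#' @param stride_duration_s stride period (s).
#' @param double_support_fraction double-support duration as a fraction of
#'   the stride, in (0, 0.5).
#' @param walking_speed_mps mean progression speed (m/s).
#' @param fs sampling rate (Hz). Event times must land on the sample grid.
#' @param total_mass_kg,height_m subject anthropometry.
#' @param vertical_amp,anterior_amp,lateral_amp force oscillation
#'   amplitudes as fractions of body weight.
#' @param sta the [sta_function()] used to split the feet (default
#'   [sta_default()]).
#' @param noise_sd_acc,noise_sd_angvel additive white Gaussian noise SD on
#'   the acceleration (m/s^2) and angular velocity (rad/s) channels.
#' @param seed RNG seed for the noise; `NULL` leaves the RNG state alone.
#' @return List of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(n_strides = 4, stride_duration_s = 1.2,
                                 double_support_fraction = 0.125,
                                 walking_speed_mps = 1.28, fs = 240,
                                 total_mass_kg = 77.34, height_m = 1.81,
                                 vertical_amp = 0.12, anterior_amp = 0.15,
                                 lateral_amp = 0.04,
                                 sta = sta_default(),
                                 noise_sd_acc = 0, noise_sd_angvel = 0,
                                 seed = NULL) {
  if (double_support_fraction <= 0 || double_support_fraction >= 0.5)
    stopf("synthetic_trial_spec: double_support_fraction must be in (0, 0.5)")
  if (stride_duration_s <= 0 || n_strides < 1)
    stopf("synthetic_trial_spec: durations must be positive")
  if (vertical_amp >= 1)
    stopf("synthetic_trial_spec: infeasible profile (vertical force would go negative)")
  for (q in c(1, 0.5, double_support_fraction)) {
    if (abs(q * stride_duration_s * fs - round(q * stride_duration_s * fs)) > 1e-9)
      stopf("synthetic_trial_spec: event times must fall on the sample grid")
  }
  structure(as.list(environment()), class = "synthetic_trial_spec")
}

#' Raised-cosine step from 0 to 1 centred at `centre` with width `width`
#' @noRd
smooth_step <- function(t, centre, width) {
  x <- (t - (centre - width / 2)) / width
  x <- pmin(1, pmax(0, x))
  (1 - cos(pi * x)) / 2
}

#' Build a speed profile from an initial level and alternating transitions
#' @noRd
speed_profile <- function(t, level0, centres, deltas, width) {
  s <- rep(level0, length(t))
  for (k in seq_along(centres)) s <- s + deltas[k] * smooth_step(t, centres[k], width)
  s
}

#' Event schedule of a symmetric synthetic gait
#' @noRd
event_schedule <- function(spec) {
  T_ <- spec$stride_duration_s; d <- spec$double_support_fraction
  t0 <- 0.5 * T_; n <- spec$n_strides
  k <- 0:n
  # an integer number of stride periods: all oscillatory position terms
  # return to their initial value, so the pelvis displacement is exactly
  # along the walking direction
  list(
    t0 = t0, duration = (n + 2) * T_,
    hs_r = t0 + k * T_, to_r = t0 + (k + 0.5 + d) * T_,
    hs_l = t0 + (k + 0.5) * T_, to_l = t0 + (k + d) * T_
  )
}

#' Generate a synthetic walking trial with exact ground truth
#'
#' @param spec a [synthetic_trial_spec()].
#' @return List of class `synthetic_trial` with elements `kinematics` (a
#'   [segment_kinematics()] including heel/toe points), `body` (the
#'   [body_model()]), `events` (ground-truth `gait_events`), `truth` (list
#'   with `total` — wrench about the origin — and per-foot `left`/`right`
#'   wrenches about their ankle projections, all noise-free), `vth` (the
#'   true threshold speed) and `spec`.
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  T_ <- spec$stride_duration_s
  fs <- spec$fs; dt <- 1 / fs
  sched <- event_schedule(spec)
  # include the endpoint sample: the trial then spans an integer number of
  # stride periods, so the oscillatory terms cancel in the first-to-last
  # pelvis displacement and the walking frame is exactly the global frame
  n <- round(sched$duration * fs) + 1L
  time <- (0:(n - 1)) * dt
  M <- spec$total_mass_kg
  g_mag <- 9.81
  v <- spec$walking_speed_mps
  body <- scale_body(M, spec$height_m, default_segment_lengths(spec$height_m),
                     instrumentation = default_instrumentation())

  # --- base trajectory: second derivative reproduces the target total force
  w_step <- 4 * pi / T_   # step frequency (two steps per stride)
  w_str <- 2 * pi / T_
  # phase offsets keep every force component away from zero at the
  # heel-strike instants, so STA normalisation is well defined
  ph_x <- pi / 3; ph_y <- pi / 4
  az <- g_mag * spec$vertical_amp * cos(w_step * time)
  ax <- g_mag * spec$anterior_amp * sin(w_step * time + ph_x)
  ay <- g_mag * spec$lateral_amp * sin(w_str * time + ph_y)
  base_pos <- cbind(v * time - g_mag * spec$anterior_amp * sin(w_step * time + ph_x) / w_step^2,
                    -g_mag * spec$lateral_amp * sin(w_str * time + ph_y) / w_str^2,
                    -g_mag * spec$vertical_amp * cos(w_step * time) / w_step^2)
  base_acc <- cbind(ax, ay, az)
  F_total <- M * cbind(ax, ay, az - rep(-g_mag, n))  # a - g with g = (0,0,-9.81)

  # --- per-segment CoM layout and antiphase internal excursions
  layout <- list(
    head = c(0, 0, 1.55), upper_trunk = c(0, 0, 1.35),
    middle_trunk = c(0, 0, 1.15), pelvis = c(0, 0, 1.00),
    upper_arm_l = c(0, 0.20, 1.35), upper_arm_r = c(0, -0.20, 1.35),
    forearm_l = c(0, 0.20, 1.05), forearm_r = c(0, -0.20, 1.05),
    hand_l = c(0, 0.20, 0.80), hand_r = c(0, -0.20, 0.80),
    upper_leg_l = c(0, 0.09, 0.85), upper_leg_r = c(0, -0.09, 0.85),
    lower_leg_l = c(0, 0.09, 0.45), lower_leg_r = c(0, -0.09, 0.45),
    foot_l = c(0, 0.09, 0.07), foot_r = c(0, -0.09, 0.07)
  )
  sway <- c(upper_arm = 0.05, forearm = 0.09, hand = 0.12,
            upper_leg = 0.06, lower_leg = 0.15, foot = 0.25)
  sway_amp <- function(nm) {
    base <- sub("_(l|r)$", "", nm)
    if (!base %in% names(sway)) return(0)
    # right leg swings with left arm: legs in antiphase with same-side arms
    leg <- base %in% c("upper_leg", "lower_leg", "foot")
    sgn <- if (endsWith(nm, "_r")) 1 else -1
    if (leg) -sgn * sway[[base]] else sgn * sway[[base]]
  }
  osc <- sin(w_str * time)
  osc_acc <- -w_str^2 * osc

  segs <- list(); com <- list(); com_acc <- list()
  zero3 <- matrix(0, n, 3)
  quat_id <- cbind(rep(1, n), 0, 0, 0)
  for (nm in names(body$segments)) {
    A <- sway_amp(nm)
    c_i <- base_pos
    c_i[, 1] <- c_i[, 1] + layout[[nm]][1] + A * osc
    c_i[, 2] <- c_i[, 2] + layout[[nm]][2]
    c_i[, 3] <- c_i[, 3] + layout[[nm]][3]
    a_i <- base_acc
    a_i[, 1] <- a_i[, 1] + A * osc_acc
    com[[nm]] <- c_i; com_acc[[nm]] <- a_i
    off <- body$segments[[nm]]$com_offset_local
    segs[[nm]] <- list(
      pos = sweep(c_i, 2, off),  # origin = CoM - R * offset, R = identity
      quat = quat_id, acc = a_i, angvel = zero3, angacc = zero3
    )
  }

  # --- ground-truth total moment about the origin (rotation-free segments)
  M0 <- matrix(0, n, 3)
  gmat <- matrix(c(0, 0, -g_mag), n, 3, byrow = TRUE)
  for (nm in names(body$segments)) {
    m_i <- body$segments[[nm]]$mass
    M0 <- M0 + cross3(com[[nm]], m_i * (com_acc[[nm]] - gmat))
  }

  # --- ankle ground projections (foot segment origins)
  ankle_l <- cbind(segs$foot_l$pos[, 1:2], 0)
  ankle_r <- cbind(segs$foot_r$pos[, 1:2], 0)

  # --- ground-truth events (all on the sample grid)
  t_index <- function(tt) as.integer(round(tt * fs)) + 1L
  ev <- rbind(
    data.frame(foot = "right", event = "heel_strike", time = sched$hs_r),
    data.frame(foot = "right", event = "toe_off", time = sched$to_r),
    data.frame(foot = "left", event = "heel_strike", time = sched$hs_l),
    data.frame(foot = "left", event = "toe_off", time = sched$to_l)
  )
  ev <- ev[ev$time < sched$duration - dt / 2, ]
  ev$index <- t_index(ev$time)
  ev <- ev[order(ev$time, ev$foot), ]
  rownames(ev) <- NULL
  events <- structure(ev, class = c("gait_events", "data.frame"),
                      vth = v, initial_state = c(left = "stance", right = "swing"))

  # --- per-foot ground truth (independent implementation of the phase table)
  truth <- split_feet_truth(time, F_total, M0, events, spec$sta, ankle_l, ankle_r)

  # --- heel/toe point speed profiles crossing the thresholds mid-sample
  vth <- v
  lead_t <- 0.05 * T_   # heel lifts / toe lands this long before TO / HS
  width <- 0.08 * T_
  mk_points <- function(hs, to, init_stance) {
    heel_lvl <- c(stance = 0.2 * vth, swing = 1.0 * vth)
    toe_lvl <- c(stance = 0.2 * vth, swing = 3.6 * vth)
    heel_tr <- rbind(
      data.frame(centre = hs - dt / 2, delta = heel_lvl[["stance"]] - heel_lvl[["swing"]]),
      data.frame(centre = to - lead_t, delta = heel_lvl[["swing"]] - heel_lvl[["stance"]])
    )
    toe_tr <- rbind(
      data.frame(centre = hs - lead_t, delta = toe_lvl[["stance"]] - toe_lvl[["swing"]]),
      data.frame(centre = to - dt / 2, delta = toe_lvl[["swing"]] - toe_lvl[["stance"]])
    )
    keep <- function(x) x[x$centre > width / 2 & x$centre < sched$duration, , drop = FALSE]
    heel_tr <- keep(heel_tr[order(heel_tr$centre), ])
    toe_tr <- keep(toe_tr[order(toe_tr$centre), ])
    lvl0 <- if (init_stance) "stance" else "swing"
    list(
      heel = speed_profile(time, heel_lvl[[lvl0]], heel_tr$centre, heel_tr$delta, width),
      toe = speed_profile(time, toe_lvl[[lvl0]], toe_tr$centre, toe_tr$delta, width)
    )
  }
  pr <- mk_points(sched$hs_r, sched$to_r, init_stance = FALSE)
  pl <- mk_points(sched$hs_l, sched$to_l, init_stance = TRUE)
  mk_point <- function(speed) {
    vel <- unname(cbind(speed, 0, 0))
    colnames(vel) <- NULL
    list(pos = apply(vel, 2, function(x) cumsum(x) * dt), vel = vel)
  }
  points <- list(heel_l = mk_point(pl$heel), toe_l = mk_point(pl$toe),
                 heel_r = mk_point(pr$heel), toe_r = mk_point(pr$toe))

  # --- noise last (ground truth stays exact)
  if (spec$noise_sd_acc > 0 || spec$noise_sd_angvel > 0) {
    for (nm in names(segs)) {
      if (spec$noise_sd_acc > 0)
        segs[[nm]]$acc <- segs[[nm]]$acc +
          matrix(stats::rnorm(3 * n, sd = spec$noise_sd_acc), n, 3)
      if (spec$noise_sd_angvel > 0)
        segs[[nm]]$angvel <- segs[[nm]]$angvel +
          matrix(stats::rnorm(3 * n, sd = spec$noise_sd_angvel), n, 3)
    }
  }

  kin <- segment_kinematics(time, segs, points)
  structure(
    list(kinematics = kin, body = body, events = events,
         truth = list(
           total = wrench_series(time, F_total, M0, c(0, 0, 0), frame = "walking"),
           left = truth$left, right = truth$right),
         ankle_l = ankle_l, ankle_r = ankle_r,
         vth = vth, spec = spec),
    class = "synthetic_trial"
  )
}

#' Ground-truth per-foot split: independent coding of the phase table
#' @noRd
split_feet_truth <- function(time, F_total, M0, events, sta, ankle_l, ankle_r) {
  n <- length(time)
  FL <- matrix(0, n, 3); ML <- matrix(0, n, 3)
  FR <- matrix(0, n, 3); MR <- matrix(0, n, 3)
  lab <- label_phases(events, time)
  m_about <- function(i, O) M0[i, ] - crossprod_vec(O, F_total[i, ])
  for (i in seq_len(n)) {
    ph <- lab[i]
    if (ph == "ss_left") {
      FL[i, ] <- F_total[i, ]; ML[i, ] <- m_about(i, ankle_l[i, ])
    } else if (ph == "ss_right") {
      FR[i, ] <- F_total[i, ]; MR[i, ] <- m_about(i, ankle_r[i, ])
    }
  }
  eps <- ds_episodes(events, time)
  for (k in seq_len(nrow(eps))) {
    i0 <- eps$start_index[k]; i1 <- eps$end_index[k]
    trail_r <- eps$trailing[k] == "right"
    O_tr <- if (trail_r) ankle_r else ankle_l
    O_ld <- if (trail_r) ankle_l else ankle_r
    M_hs <- m_about(i0, O_tr[i0, ])
    F_hs <- F_total[i0, ]
    for (i in i0:(i1 - 1L)) {
      tau <- (time[i] - time[i0]) / (time[i1] - time[i0])
      s <- evaluate_sta(sta, tau)
      f_tr <- s[1, 1:3] * F_hs
      m_tr <- s[1, 4:6] * M_hs + crossprod_vec(O_tr[i0, ] - O_tr[i, ], f_tr)
      f_ld <- F_total[i, ] - f_tr
      m_ld <- m_about(i, O_tr[i, ]) - m_tr +
        crossprod_vec(O_tr[i, ] - O_ld[i, ], f_ld)
      if (trail_r) {
        FR[i, ] <- f_tr; MR[i, ] <- m_tr; FL[i, ] <- f_ld; ML[i, ] <- m_ld
      } else {
        FL[i, ] <- f_tr; ML[i, ] <- m_tr; FR[i, ] <- f_ld; MR[i, ] <- m_ld
      }
    }
  }
  list(left = wrench_series(time, FL, ML, ankle_l, frame = "walking"),
       right = wrench_series(time, FR, MR, ankle_r, frame = "walking"))
}

#' Generate a static upright trial (zero motion)
#'
#' All velocities and accelerations are zero; the ground-truth total
#' external force is the body weight pointing up, split between the feet by
#' `stance_split`.
#'
#' @param total_mass_kg,height_m subject anthropometry.
#' @param duration_s trial duration (default 2 s).
#' @param fs sampling rate (Hz).
#' @param stance_split fraction of load on the left foot (default 0.5).
#' @return List of class `synthetic_trial` (without events: no gait).
#' @export
generate_static_pose <- function(total_mass_kg = 77.34, height_m = 1.81,
                                 duration_s = 2, fs = 240, stance_split = 0.5) {
  body <- scale_body(total_mass_kg, height_m, default_segment_lengths(height_m),
                     instrumentation = default_instrumentation())
  n <- round(duration_s * fs)
  time <- (0:(n - 1)) / fs
  zero3 <- matrix(0, n, 3)
  quat_id <- cbind(rep(1, n), 0, 0, 0)
  layout_z <- c(head = 1.55, upper_trunk = 1.35, middle_trunk = 1.15,
                pelvis = 1.00, upper_arm = 1.35, forearm = 1.05, hand = 0.80,
                upper_leg = 0.85, lower_leg = 0.45, foot = 0.07)
  segs <- list()
  for (nm in names(body$segments)) {
    base <- sub("_(l|r)$", "", nm)
    y <- if (endsWith(nm, "_l")) 0.1 else if (endsWith(nm, "_r")) -0.1 else 0
    off <- body$segments[[nm]]$com_offset_local
    pos <- matrix(rep(c(0, y, layout_z[[base]]) - off, each = n), n, 3)
    segs[[nm]] <- list(pos = pos, quat = quat_id, acc = zero3,
                       angvel = zero3, angacc = zero3)
  }
  F_total <- cbind(0, 0, rep(total_mass_kg * 9.81, n))
  M0 <- matrix(0, n, 3)
  for (nm in names(body$segments)) {
    com1 <- segs[[nm]]$pos[1, ] + body$segments[[nm]]$com_offset_local
    M0 <- M0 + matrix(crossprod_vec(com1, body$segments[[nm]]$mass * c(0, 0, 9.81)),
                      n, 3, byrow = TRUE)
  }
  kin <- segment_kinematics(time, segs)
  fl <- F_total * stance_split
  fr <- F_total * (1 - stance_split)
  structure(
    list(kinematics = kin, body = body, events = NULL,
         truth = list(
           total = wrench_series(time, F_total, M0, frame = "walking"),
           left = wrench_series(time, fl, frame = "walking"),
           right = wrench_series(time, fr, frame = "walking")),
         vth = 0, spec = list(total_mass_kg = total_mass_kg, height_m = height_m)),
    class = "synthetic_trial"
  )
}
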