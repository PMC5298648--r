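# Segment kinematics container and preparation: zero-phase low-pass
# filtering, angular-velocity differentiation, translation of origin
# accelerations to the segment centre of mass, and the walking frame.

#' Segment kinematics time series
#'
#' Container for per-segment rigid-body kinematics on a uniform time grid.
#' Each segment holds its origin position `pos` (n x 3, m), orientation
#' `quat` (n x 4 unit quaternions, order w,x,y,z, segment-to-global), origin
#' linear acceleration `acc` (n x 3, m/s^2), angular velocity `angvel`
#' (n x 3, rad/s) and optionally angular acceleration `angacc` (n x 3,
#' rad/s^2). All free vectors are expressed in the global frame. `points`
#' optionally carries tracked ground-contact points (heel/toe) as lists with
#' `pos` and optionally `vel`.
#'
#' @param time numeric vector (s), uniform grid.
#' @param segments named list of segment channel lists (see above).
#' @param points named list of point channel lists, may be empty.
#' @return Object of class `segment_kinematics`.
#' @export
segment_kinematics <- function(time, segments, points = list()) {
  if (!is_uniform_grid(time))
    stopf("segment_kinematics: time grid is not uniform")
  n <- length(time)
  for (nm in names(segments)) {
    s <- segments[[nm]]
    for (ch in c("pos", "quat", "acc", "angvel")) {
      if (is.null(s[[ch]]))
        stopf("segment_kinematics: segment '%s' lacks channel '%s'", nm, ch)
      if (nrow(s[[ch]]) != n)
        stopf("segment_kinematics: segment '%s' channel '%s' length mismatch", nm, ch)
      if (anyNA(s[[ch]]))
        stopf("segment_kinematics: segment '%s' channel '%s' has missing samples", nm, ch)
    }
    qn <- sqrt(rowSums(s$quat^2))
    if (max(abs(qn - 1)) > 1e-6)
      stopf("segment_kinematics: segment '%s' quaternions are not unit-norm", nm)
  }
  fs <- if (n > 1) 1 / (time[2] - time[1]) else NA_real_
  structure(list(time = time, fs = fs, segments = segments, points = points),
            class = "segment_kinematics")
}

#' @export
print.segment_kinematics <- function(x, ...) {
  cat(sprintf("<segment_kinematics> %d samples @ %.6g Hz, %d segments, %d points\n",
              length(x$time), x$fs, length(x$segments), length(x$points)))
  invisible(x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass design forward and backward
#' (zero phase; squared magnitude response) channel-wise. Edge transients
#' are controlled with odd-symmetric signal extension before each pass, so
#' the DC gain is exactly 1: a constant signal passes through unchanged.
#'
#' @param x numeric vector or matrix (channels in columns).
#' @param cutoff_hz cut-off frequency (Hz), must be below the Nyquist rate.
#' @param fs sampling rate (Hz).
#' @param order filter order of a single pass (default 2).
#' @return Filtered signal, same shape as `x`.
#' @export
lowpass_filter <- function(x, cutoff_hz, fs, order = 2) {
  if (cutoff_hz >= fs / 2)
    stopf("lowpass_filter: cutoff (%g Hz) must be below Nyquist (%g Hz)",
          cutoff_hz, fs / 2)
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  bf <- signal::butter(order, 2 * cutoff_hz / fs, type = "low")
  # the odd-symmetric extension must outlast the filter transient, which
  # decays on the scale of fs / cutoff samples
  pad <- max(3L * max(length(bf$b), length(bf$a)),
             ceiling(6 * fs / cutoff_hz))
  n <- nrow(xm)
  if (n <= pad)
    stopf("lowpass_filter: series too short (%d samples) for filter warm-up (%d)",
          n, pad)
  out <- apply(xm, 2, function(col) {
    ext <- c(2 * col[1] - col[(pad + 1):2],
             col,
             2 * col[n] - col[(n - 1):(n - pad)])
    y <- signal::filter(bf, ext)
    y <- rev(signal::filter(bf, rev(y)))
    y[(pad + 1):(pad + n)]
  })
  if (vec) as.numeric(out) else out
}

#' Filter the dynamic channels of a kinematics series
#'
#' Applies [lowpass_filter()] to the angular velocity, angular acceleration
#' and origin linear acceleration of every segment, and to any point
#' velocities present. Positions and orientations are left untouched.
#'
#' @param kin a [segment_kinematics()] object.
#' @param cutoff_hz,order filter settings (defaults 6 Hz, order 2).
#' @return The filtered `segment_kinematics`.
#' @export
filter_kinematics <- function(kin, cutoff_hz = 6, order = 2) {
  fs <- kin$fs
  for (nm in names(kin$segments)) {
    for (ch in c("acc", "angvel", "angacc")) {
      if (!is.null(kin$segments[[nm]][[ch]]))
        kin$segments[[nm]][[ch]] <-
          lowpass_filter(kin$segments[[nm]][[ch]], cutoff_hz, fs, order)
    }
  }
  for (nm in names(kin$points)) {
    if (!is.null(kin$points[[nm]]$vel))
      kin$points[[nm]]$vel <-
        lowpass_filter(kin$points[[nm]]$vel, cutoff_hz, fs, order)
  }
  kin
}

#' Fill angular accelerations by differentiating angular velocities
#'
#' Central finite differences on the uniform grid, one-sided at the
#' endpoints. Segments that already carry `angacc` are left unchanged
#' unless `overwrite = TRUE`. Differentiation amplifies high-frequency
#' content; run [filter_kinematics()] afterwards.
#'
#' @param kin a [segment_kinematics()] object.
#' @param overwrite recompute even when `angacc` is present.
#' @return `kin` with `angacc` present on every segment.
#' @export
differentiate_angular_velocity <- function(kin, overwrite = FALSE) {
  dt <- 1 / kin$fs
  if (length(kin$time) < 3L)
    stopf("differentiate_angular_velocity: need at least 3 samples")
  for (nm in names(kin$segments)) {
    if (is.null(kin$segments[[nm]]$angacc) || overwrite)
      kin$segments[[nm]]$angacc <- central_diff(kin$segments[[nm]]$angvel, dt)
  }
  kin
}

#' Translate origin accelerations to the segment centre of mass
#'
#' Rigid-body acceleration transfer:
#' `a_com = a_origin + angacc x r + angvel x (angvel x r)`, with `r` the
#' origin-to-CoM vector expressed in the global frame.
#'
#' @param a_origin n x 3 origin linear acceleration (global frame, m/s^2).
#' @param angvel,angacc n x 3 angular velocity (rad/s) and acceleration
#'   (rad/s^2) in the global frame.
#' @param r_global n x 3 (or length-3) origin-to-CoM vector in the global
#'   frame (m).
#' @return n x 3 CoM acceleration (m/s^2).
#' @export
translate_acceleration_to_com <- function(a_origin, angvel, angacc, r_global) {
  if (is.null(dim(r_global)))
    r_global <- matrix(r_global, nrow = nrow(a_origin), ncol = 3, byrow = TRUE)
  a_origin + cross3(angacc, r_global) +
    cross3(angvel, cross3(angvel, r_global))
}

#' Walking coordinate frame from pelvis displacement
#'
#' The walking frame shares the vertical axis of the global frame; its
#' anterior axis points along the horizontal displacement of the pelvis
#' between the first and last sample (straight-line walking assumed). The
#' returned yaw rotation maps global-frame vectors into the walking frame
#' and leaves the vertical axis exactly fixed.
#'
#' @param pelvis_positions n x 3 pelvis origin positions (global frame, m).
#' @param min_displacement_m minimum horizontal displacement below which the
#'   walking direction is undefined (default 0.5 m).
#' @return A list with `yaw_rotation` (3 x 3 matrix, global to walking) and
#'   `heading_rad`.
#' @export
walking_frame <- function(pelvis_positions, min_displacement_m = 0.5) {
  d <- pelvis_positions[nrow(pelvis_positions), 1:2] - pelvis_positions[1, 1:2]
  if (sqrt(sum(d^2)) < min_displacement_m)
    stopf("walking_frame: walking direction undefined (horizontal displacement %.3f m < %.3f m)",
          sqrt(sum(d^2)), min_displacement_m)
  heading <- atan2(d[2], d[1])
  R <- matrix(c(cos(heading), sin(heading), 0,
                -sin(heading), cos(heading), 0,
                0, 0, 1), nrow = 3, byrow = TRUE)
  list(yaw_rotation = R, heading_rad = heading)
}
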