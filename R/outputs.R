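# Centre of pressure, frictional torque and the normalisations applied to
# per-foot ground reaction wrenches before comparison.

#' Centre of pressure from a per-foot wrench
#'
#' With the wrench expressed in the walking frame about the foot's ankle
#' ground projection: `COPx = -My / Fz`, `COPy = Mx / Fz`, `COPz = 0`.
#' Samples with vertical force at or below the threshold are masked (the
#' foot is not meaningfully loaded there).
#'
#' @param wrench a [wrench_series()] in the walking frame about the ankle
#'   ground projection.
#' @param fz_threshold_N minimum vertical force for a valid COP (default 5 N).
#' @return List of class `cop_series`: `time`, `cop` (n x 2, anterior and
#'   lateral, m; `NA` where invalid), `valid_mask`.
#' @export
compute_cop <- function(wrench, fz_threshold_N = 5) {
  fz <- wrench$force[, 3]
  valid <- fz > fz_threshold_N
  cop <- matrix(NA_real_, length(fz), 2, dimnames = list(NULL, c("x", "y")))
  cop[valid, 1] <- -wrench$moment[valid, 2] / fz[valid]
  cop[valid, 2] <- wrench$moment[valid, 1] / fz[valid]
  structure(list(time = wrench$time, cop = cop, valid_mask = valid),
            class = "cop_series")
}

#' Frictional torque about the centre of pressure
#'
#' The vertical moment remaining once the wrench acts at the COP:
#' `T_F = Mz - COPx * Fy + COPy * Fx`. `NA` where the COP is masked.
#'
#' @param wrench a [wrench_series()] about the ankle ground projection.
#' @param cop a [compute_cop()] result for the same wrench.
#' @return Numeric vector (N m).
#' @export
compute_frictional_torque <- function(wrench, cop) {
  wrench$moment[, 3] - cop$cop[, 1] * wrench$force[, 2] +
    cop$cop[, 2] * wrench$force[, 1]
}

#' Normalize a wrench to body weight and body weight times height
#'
#' Forces are divided by `m g` (units of body weight, BW) and moments by
#' `m g h` (units of BW * BH). Exactly invertible.
#'
#' @param wrench a [wrench_series()].
#' @param body_mass_kg,height_m subject mass (kg) and stature (m).
#' @param g gravitational acceleration magnitude (default 9.81 m/s^2).
#' @return The normalized `wrench_series` (same reference points).
#' @export
normalize_wrench <- function(wrench, body_mass_kg, height_m, g = 9.81) {
  if (body_mass_kg <= 0 || height_m <= 0)
    stopf("normalize_wrench: mass and height must be positive")
  bw <- body_mass_kg * g
  wrench_series(wrench$time, wrench$force / bw, wrench$moment / (bw * height_m),
                wrench$ref_point, wrench$frame)
}

#' Resample a curve onto the percent-of-gait-cycle grid
#'
#' Linear interpolation of each column onto `n_points` equally spaced
#' samples between two consecutive ipsilateral heel strikes (0 to 100% of
#' the gait cycle).
#'
#' @param x numeric vector or matrix (samples in rows).
#' @param time time grid of `x` (s).
#' @param t_start,t_end cycle boundaries (s).
#' @param n_points number of output samples (default 101, i.e. 0..100%).
#' @return Matrix `n_points x ncol(x)` (vector in, vector out).
#' @export
time_normalize <- function(x, time, t_start, t_end, n_points = 101) {
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  inside <- sum(time >= t_start & time <= t_end)
  if (inside < 3) stopf("time_normalize: cycle spans fewer than 3 samples")
  grid <- seq(t_start, t_end, length.out = n_points)
  out <- vapply(seq_len(ncol(xm)), function(j)
    stats::approx(time, xm[, j], xout = grid)$y, numeric(n_points))
  if (vec) as.numeric(out) else out
}
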