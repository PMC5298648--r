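# Smooth transition assumption (STA): six shape curves on normalized
# double-support time tau in [0, 1] that scale the trailing foot's wrench
# from its value at the contralateral heel strike (tau = 0, factor 1) down
# to zero at the ipsilateral toe-off (tau = 1). Curve sets are data:
# represented as tabulated knots interpolated by a cubic spline, and
# re-creatable from measured per-foot wrenches via calibrate_sta().

STA_COMPONENTS <- c("F_anterior", "F_lateral", "F_vertical",
                    "M_frontal", "M_sagittal", "M_transverse")

#' Construct an STA function from knot tables
#'
#' @param tau knot locations in `[0, 1]` (must include 0 and 1).
#' @param values matrix `length(tau) x 6` of knot values, columns in the
#'   order anterior/lateral/vertical force, frontal/sagittal/transverse
#'   moment. Row at `tau = 0` must be 1, at `tau = 1` must be 0.
#' @param source free-text provenance tag.
#' @return Object of class `sta_function`.
#' @export
sta_function <- function(tau, values, source = "custom") {
  values <- as.matrix(values)
  if (ncol(values) != 6) stopf("sta_function: expected 6 component columns")
  if (abs(tau[1]) > 1e-12 || abs(tau[length(tau)] - 1) > 1e-12)
    stopf("sta_function: knots must span [0, 1]")
  if (max(abs(values[1, ] - 1)) > 1e-9 || max(abs(values[nrow(values), ])) > 1e-9)
    stopf("sta_function: endpoint values must be exactly 1 at tau=0 and 0 at tau=1")
  colnames(values) <- STA_COMPONENTS
  splines <- lapply(seq_len(6), function(j)
    stats::splinefun(tau, values[, j], method = "natural"))
  structure(list(tau = tau, values = values, splines = splines, source = source),
            class = "sta_function")
}

#' @export
print.sta_function <- function(x, ...) {
  cat(sprintf("<sta_function> %d knots on [0,1], source '%s'\n",
              length(x$tau), x$source))
  invisible(x)
}

#' Default smooth transition curves
#'
#' A raised-cosine smooth step, `f(tau) = (1 + cos(pi tau)) / 2`, used for
#' all six components: continuously differentiable, equal to 1 with zero
#' slope at the contralateral heel strike and to 0 with zero slope at
#' toe-off. Tabulated at `n_knots` equally spaced knots and interpolated by
#' a natural cubic spline, like any calibrated curve set.
#'
#' @param n_knots number of knots (default 21).
#' @return An [sta_function()].
#' @export
sta_default <- function(n_knots = 21) {
  tau <- seq(0, 1, length.out = n_knots)
  v <- (1 + cos(pi * tau)) / 2
  v[1] <- 1; v[n_knots] <- 0
  sta_function(tau, matrix(v, n_knots, 6), source = "raised-cosine default")
}

#' Evaluate STA scale factors
#'
#' @param sta an [sta_function()].
#' @param tau normalized double-support time(s) in `[0, 1]`.
#' @return `length(tau) x 6` matrix of scale factors; exactly 1 at
#'   `tau = 0` and 0 at `tau = 1`.
#' @export
evaluate_sta <- function(sta, tau) {
  if (any(tau < -1e-12 | tau > 1 + 1e-12))
    stopf("evaluate_sta: tau outside [0, 1]")
  tau <- pmin(1, pmax(0, tau))
  out <- vapply(sta$splines, function(f) f(tau), numeric(length(tau)))
  out <- matrix(out, nrow = length(tau), ncol = 6,
                dimnames = list(NULL, STA_COMPONENTS))
  out[tau == 0, ] <- 1
  out[tau == 1, ] <- 0
  out
}

#' Calibrate STA curves from measured per-foot wrenches
#'
#' For every double-support episode in `events`, takes the trailing foot's
#' measured wrench (expressed in the walking frame about its ankle
#' projection), normalizes each of the six components by its value at the
#' contralateral heel strike, resamples it onto a common normalized-time
#' grid, averages across episodes, clamps the endpoints to 1 and 0 and fits
#' a natural cubic spline through the mean curve.
#'
#' @param left,right [wrench_series()] of measured per-foot wrenches in the
#'   walking frame.
#' @param events a `gait_events` table for the same time grid.
#' @param time time grid shared by the wrenches.
#' @param n_knots number of spline knots of the result (default 21).
#' @param min_start_magnitude episodes whose component magnitude at the
#'   heel strike is below this (N or N m) are excluded with a warning.
#' @return An [sta_function()] with attribute `n_episodes`.
#' @export
calibrate_sta <- function(left, right, events, time, n_knots = 21,
                          min_start_magnitude = 1e-8) {
  eps <- ds_episodes(events, time)
  if (!nrow(eps)) stopf("calibrate_sta: no double-support episodes in events")
  tau_grid <- seq(0, 1, length.out = 101)
  acc <- matrix(0, length(tau_grid), 6)
  used <- 0L
  for (k in seq_len(nrow(eps))) {
    w <- if (eps$trailing[k] == "left") left else right
    idx <- eps$start_index[k]:eps$end_index[k]
    # the STA scaling is defined about the trailing ankle projection at the
    # heel strike: undo the per-sample reference point before normalizing
    ref0 <- w$ref_point[idx[1], ]
    moment_fixed <- w$moment[idx, , drop = FALSE] +
      cross3(w$ref_point[idx, , drop = FALSE] -
               matrix(ref0, length(idx), 3, byrow = TRUE),
             w$force[idx, , drop = FALSE])
    comp <- cbind(w$force[idx, , drop = FALSE], moment_fixed)
    start_vals <- comp[1, ]
    if (any(abs(start_vals) < min_start_magnitude)) {
      warnf("calibrate_sta: episode %d has near-zero wrench at heel strike; excluded", k)
      next
    }
    tau <- (time[idx] - time[idx[1]]) / (time[idx[length(idx)]] - time[idx[1]])
    resampled <- vapply(seq_len(6), function(j)
      stats::approx(tau, comp[, j] / start_vals[j], xout = tau_grid)$y,
      numeric(length(tau_grid)))
    acc <- acc + resampled
    used <- used + 1L
  }
  if (!used) stopf("calibrate_sta: no usable double-support episodes")
  mean_curve <- acc / used
  knot_tau <- seq(0, 1, length.out = n_knots)
  knots <- vapply(seq_len(6), function(j)
    stats::approx(tau_grid, mean_curve[, j], xout = knot_tau)$y,
    numeric(n_knots))
  knots[1, ] <- 1
  knots[n_knots, ] <- 0
  out <- sta_function(knot_tau, knots,
                      source = sprintf("calibrated from %d episodes", used))
  attr(out, "n_episodes") <- used
  out
}

#' Double-support episodes of an event table
#'
#' Each episode runs from a heel strike of the leading foot to the next
#' toe-off of the trailing (other) foot.
#'
#' @param events a `gait_events` table.
#' @param time the underlying time grid.
#' @return Data.frame with `start_index`, `end_index`, `start_time`,
#'   `end_time`, `leading`, `trailing`.
#' @export
ds_episodes <- function(events, time) {
  lab <- label_phases(events, time)
  sl <- attr(lab, "stance_left"); sr <- attr(lab, "stance_right")
  both <- sl & sr
  rows <- list()
  if (any(both)) {
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    for (k in which(r$values)) {
      i0 <- starts[k]
      i1 <- min(ends[k] + 1L, length(time))  # first sample after DS = trailing toe-off
      lead <- if (lab[i0] == "ds_lead_left") "left" else "right"
      if (i1 <= i0) next
      rows[[length(rows) + 1L]] <- data.frame(
        start_index = i0, end_index = i1,
        start_time = time[i0], end_time = time[i1],
        leading = lead, trailing = if (lead == "left") "right" else "left")
    }
  }
  if (!length(rows))
    return(data.frame(start_index = integer(0), end_index = integer(0),
                      start_time = numeric(0), end_time = numeric(0),
                      leading = character(0), trailing = character(0)))
  do.call(rbind, rows)
}
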