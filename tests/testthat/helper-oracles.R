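# Shared fixtures, all built in code.

.fixture_cache <- new.env(parent = emptyenv())

#' Memoized synthetic trial (generation is deterministic, reuse across files)
cached_trial <- function(key = "default") {
  if (is.null(.fixture_cache[[key]])) {
    spec <- switch(key,
      default = synthetic_trial_spec(n_strides = 3),
      long = synthetic_trial_spec(n_strides = 25),
      noisy = synthetic_trial_spec(n_strides = 3, noise_sd_acc = 0.5,
                                   noise_sd_angvel = 0.05, seed = 42),
      stop("unknown fixture key")
    )
    .fixture_cache[[key]] <- generate_trial(spec)
  }
  .fixture_cache[[key]]
}

#' Analytic 3-link planar pendulum chain with prescribed sinusoidal joint
#' angles about the global y-axis. All derivatives are closed form; the
#' reaction wrench at the support is the independent oracle the package's
#' Newton-Euler path is checked against.
make_pendulum <- function(fs = 240, duration = 2) {
  time <- seq(0, duration, by = 1 / fs)
  n <- length(time)
  L <- c(0.4, 0.35, 0.25); lam <- c(0.45, 0.4, 0.5); m <- c(7, 3.5, 1.1)
  Jloc <- list(diag(c(0.08, 0.06, 0.01)), diag(c(0.04, 0.035, 0.004)),
               diag(c(0.006, 0.005, 0.001)))
  A <- c(0.5, 0.8, 1.1); fr <- c(0.7, 1.1, 1.6); ph <- c(0, 1, 2)
  th <- sapply(1:3, function(k) A[k] * sin(2 * pi * fr[k] * time + ph[k]))
  thd <- sapply(1:3, function(k) A[k] * 2 * pi * fr[k] * cos(2 * pi * fr[k] * time + ph[k]))
  thdd <- sapply(1:3, function(k) -A[k] * (2 * pi * fr[k])^2 * sin(2 * pi * fr[k] * time + ph[k]))
  u <- function(k) cbind(sin(th[, k]), 0, -cos(th[, k]))
  udd <- function(k) cbind(cos(th[, k]) * thdd[, k] - sin(th[, k]) * thd[, k]^2, 0,
                           sin(th[, k]) * thdd[, k] + cos(th[, k]) * thd[, k]^2)
  p <- list(matrix(0, n, 3)); a_jt <- list(matrix(0, n, 3))
  for (k in 1:3) {
    p[[k + 1]] <- p[[k]] + L[k] * u(k)
    a_jt[[k + 1]] <- a_jt[[k]] + L[k] * udd(k)
  }
  com <- lapply(1:3, function(k) p[[k]] + lam[k] * L[k] * u(k))
  acc <- lapply(1:3, function(k) a_jt[[k]] + lam[k] * L[k] * udd(k))
  g <- c(0, 0, -9.81)
  gm <- matrix(g, n, 3, byrow = TRUE)
  F_oracle <- Reduce(`+`, lapply(1:3, function(k) m[k] * (acc[[k]] - gm)))
  cross_rows <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                     a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                     a[, 1] * b[, 2] - a[, 2] * b[, 1])
  M_oracle <- Reduce(`+`, lapply(1:3, function(k) {
    euler <- cbind(0, Jloc[[k]][2, 2] * (-thdd[, k]), 0)  # rotation about y
    euler + cross_rows(com[[k]], m[k] * (acc[[k]] - gm))
  }))
  alpha <- pi - th
  segs <- list(); seglist <- list()
  for (k in 1:3) {
    nm <- paste0("link", k)
    segs[[nm]] <- list(pos = p[[k]],
                       quat = cbind(cos(alpha[, k] / 2), 0, sin(alpha[, k] / 2), 0),
                       acc = a_jt[[k]],
                       angvel = cbind(0, -thd[, k], 0),
                       angacc = cbind(0, -thdd[, k], 0))
    seglist[[k]] <- list(name = nm, mass = m[k], length = L[k],
                         com_offset_local = c(0, 0, lam[k] * L[k]),
                         inertia_com_local = Jloc[[k]])
  }
  list(body = body_model(seglist), kin = segment_kinematics(time, segs),
       F_oracle = F_oracle, M_oracle = M_oracle, time = time)
}

#' Hand-built single double-support episode: both feet grounded on an
#' overlap window, trailing-foot wrench decaying linearly to zero.
linear_ds_fixture <- function(n = 121, fs = 100) {
  time <- (0:(n - 1)) / fs
  hs_l <- 21L; to_r <- 81L
  events <- structure(
    data.frame(foot = c("left", "right"), event = c("heel_strike", "toe_off"),
               time = time[c(hs_l, to_r)], index = c(hs_l, to_r)),
    class = c("gait_events", "data.frame"),
    initial_state = c(left = "swing", right = "stance"))
  F0 <- c(40, -20, 600); M0 <- c(12, -30, 4)
  decay <- pmax(0, pmin(1, (time[to_r] - time) / (time[to_r] - time[hs_l])))
  right <- wrench_series(time, outer(decay, F0), outer(decay, M0),
                         frame = "walking")
  left <- wrench_series(time, -outer(decay, F0) + matrix(F0, n, 3, byrow = TRUE),
                        frame = "walking")
  list(time = time, events = events, left = left, right = right,
       hs_l = hs_l, to_r = to_r)
}
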