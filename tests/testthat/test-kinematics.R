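test_that("zero-phase filter preserves DC and attenuates as designed", {
  fs <- 240; t <- (0:2399) / fs
  # constant signal passes unchanged
  expect_equal(lowpass_filter(rep(3.7, length(t)), 6, fs), rep(3.7, length(t)),
               tolerance = 1e-9)
  # sine at the cut-off: two passes leave (1/sqrt(2))^2 = 0.5 of the amplitude
  x <- sin(2 * pi * 6 * t)
  y <- lowpass_filter(x, 6, fs)
  interior <- 400:2000
  expect_equal(max(abs(y[interior])), 0.5, tolerance = 0.02)
  # far above the cut-off: essentially eliminated
  z <- lowpass_filter(sin(2 * pi * 60 * t), 6, fs)
  expect_lt(max(abs(z[interior])), 1e-3)
  expect_error(lowpass_filter(x, 120, fs), "Nyquist")
})

test_that("angular velocity differentiation is exact for linear signals and
           bounded for sines", {
  fs <- 240; t <- (0:719) / fs
  kin_of <- function(w) {
    segment_kinematics(t, list(seg = list(
      pos = matrix(0, length(t), 3), quat = cbind(1, 0, 0, 0) [rep(1, length(t)), ],
      acc = matrix(0, length(t), 3), angvel = w)))
  }
  # linear ramp: exact at interior samples (and at one-sided endpoints)
  w <- cbind(2.5 * t, -1.1 * t, 0 * t)
  d <- differentiate_angular_velocity(kin_of(w))$segments$seg$angacc
  expect_equal(d[2:(length(t) - 1), 1], rep(2.5, length(t) - 2), tolerance = 1e-9)
  expect_equal(d[5, 2], -1.1, tolerance = 1e-9)
  # constant: zero derivative
  d0 <- differentiate_angular_velocity(kin_of(matrix(1, length(t), 3)))$segments$seg$angacc
  expect_equal(max(abs(d0)), 0)
  # sine at f: interior error below the Taylor remainder bound (2 pi f)^3 / (6 fs^2)
  f <- 3
  ws <- cbind(sin(2 * pi * f * t), 0, 0)
  ds <- differentiate_angular_velocity(kin_of(ws))$segments$seg$angacc
  truth <- 2 * pi * f * cos(2 * pi * f * t)
  err <- abs(ds[2:(length(t) - 1), 1] - truth[2:(length(t) - 1)])
  expect_lt(max(err), (2 * pi * f)^3 / (6 * fs^2))
})

test_that("acceleration transfer to the CoM matches closed forms and a
           finite-difference oracle", {
  n <- 5
  z3 <- matrix(0, n, 3)
  # coincident points
  a <- matrix(rnorm(3 * n), n, 3)
  expect_equal(translate_acceleration_to_com(a, z3, z3, c(0, 0, 0)), a)
  # centripetal: omega = (0,0,Om), r = (R,0,0) -> a = (-Om^2 R, 0, 0)
  Om <- 3; R <- 0.4
  w <- matrix(c(0, 0, Om), n, 3, byrow = TRUE)
  ac <- translate_acceleration_to_com(z3, w, z3, c(R, 0, 0))
  expect_equal(ac, matrix(c(-Om^2 * R, 0, 0), n, 3, byrow = TRUE))
  # finite-difference oracle on a spinning+translating trajectory
  fs <- 2000; t <- (0:4000) / fs
  ang <- 1.3 * sin(2 * pi * 0.8 * t) + 0.4 * t
  angd <- 1.3 * 2 * pi * 0.8 * cos(2 * pi * 0.8 * t) + 0.4
  angdd <- -1.3 * (2 * pi * 0.8)^2 * sin(2 * pi * 0.8 * t)
  r_loc <- c(0.25, -0.1, 0.05)
  # rotation about global z
  Rt <- function(th) matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)
  p0 <- cbind(0.5 * t^2, sin(t), 0 * t)
  pos <- t(vapply(seq_along(t), function(i) p0[i, ] + Rt(ang[i]) %*% r_loc,
                  numeric(3)))
  a_num <- (pos[3:length(t), ] - 2 * pos[2:(length(t) - 1), ] +
              pos[1:(length(t) - 2), ]) * fs^2
  a0 <- cbind(rep(1, length(t)), -sin(t), 0)
  wz <- cbind(0, 0, angd); wdz <- cbind(0, 0, angdd)
  r_glob <- t(vapply(seq_along(t), function(i) as.numeric(Rt(ang[i]) %*% r_loc),
                     numeric(3)))
  a_com <- translate_acceleration_to_com(a0, wz, wdz, r_glob)
  expect_equal(a_com[2:(length(t) - 1), ], a_num, tolerance = 1e-4)
})

test_that("walking frame is a pure yaw following the pelvis displacement", {
  t <- seq(0, 5, by = 1 / 60)
  straight <- cbind(1.3 * t, 0 * t, 1 + 0.02 * sin(t))
  wf <- walking_frame(straight)
  expect_equal(wf$yaw_rotation, diag(3), tolerance = 1e-12)
  # +y walk: 90 degree yaw, vertical exactly fixed
  wf90 <- walking_frame(cbind(0 * t, 1.3 * t, 1 + 0 * t))
  expect_equal(wf90$heading_rad, pi / 2)
  expect_equal(as.numeric(wf90$yaw_rotation %*% c(0, 0, 1)), c(0, 0, 1))
  # diagonal 30 degrees: transformed velocity has zero mean lateral component
  th <- pi / 6
  diag30 <- cbind(1.3 * t * cos(th), 1.3 * t * sin(th), 1 + 0 * t)
  wfd <- walking_frame(diag30)
  v <- (diag30[-1, ] - diag30[-nrow(diag30), ]) * 60
  vw <- v %*% t(wfd$yaw_rotation)
  expect_equal(mean(vw[, 2]), 0, tolerance = 1e-12)
  expect_gt(mean(vw[, 1]), 0)
  # stationary: undefined direction
  expect_error(walking_frame(cbind(0 * t, 0 * t, 1 + 0 * t)),
               "walking direction undefined")
})

test_that("filtering commutes with a fixed frame rotation", {
  set.seed(3)
  fs <- 240; n <- 720
  x <- matrix(rnorm(3 * n), n, 3)
  x <- apply(x, 2, cumsum)  # smooth-ish random walk
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  a <- lowpass_filter(x %*% t(R), 6, fs)
  b <- lowpass_filter(x, 6, fs) %*% t(R)
  expect_lt(max(abs(a - b)), 1e-9)
})
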