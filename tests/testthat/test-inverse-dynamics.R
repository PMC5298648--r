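test_that("a static pose yields body weight upward and zero force in free fall", {
  st <- generate_static_pose(total_mass_kg = 77.34)
  Fw <- total_external_force(st$body, st$kinematics)
  expect_equal(Fw$force[1, ], c(0, 0, 77.34 * 9.81))
  expect_equal(Fw$force[1, 3], 758.7, tolerance = 0.01)
  expect_equal(max(abs(Fw$force[, 1:2])), 0)
  # free fall: every CoM accelerates at g
  kin <- st$kinematics
  n <- length(kin$time)
  for (nm in names(kin$segments))
    kin$segments[[nm]]$acc <- matrix(c(0, 0, -9.81), n, 3, byrow = TRUE)
  expect_equal(max(abs(total_external_force(st$body, kin)$force)), 0)
})

test_that("Newton-Euler wrench matches the analytic pendulum-chain oracle", {
  pen <- make_pendulum()
  tw <- total_external_moment(pen$body, pen$kin, ref_point = c(0, 0, 0))
  expect_lt(max(abs(tw$force - pen$F_oracle)) / max(abs(pen$F_oracle)), 1e-8)
  expect_lt(max(abs(tw$moment - pen$M_oracle)) / max(abs(pen$M_oracle)), 1e-8)
})

test_that("single-segment Euler terms: steady spin is torque-free, angular
           acceleration gives J alpha", {
  fs <- 240; t <- (0:479) / fs; n <- length(t)
  J <- diag(c(0.05, 0.08, 0.11))
  mkkin <- function(angvel, angacc, quat) {
    segment_kinematics(t, list(rotor = list(
      pos = matrix(0, n, 3), quat = quat, acc = matrix(0, n, 3),
      angvel = angvel, angacc = angacc)))
  }
  body <- body_model(list(list(name = "rotor", mass = 2, length = 0.3,
                               com_offset_local = c(0, 0, 0),
                               inertia_com_local = J)),
                     gravity = c(0, 0, 0))
  # steady spin about the principal z axis, orientation following the spin
  Om <- 5
  quat <- cbind(cos(Om * t / 2), 0, 0, sin(Om * t / 2))
  w <- matrix(c(0, 0, Om), n, 3, byrow = TRUE)
  tw <- total_external_moment(body, mkkin(w, matrix(0, n, 3), quat))
  expect_lt(max(abs(tw$moment)), 1e-10)
  # angular acceleration about principal z at identity orientation
  alpha <- 3
  tw2 <- total_external_moment(body, mkkin(
    matrix(0, n, 3), matrix(c(0, 0, alpha), n, 3, byrow = TRUE),
    cbind(rep(1, n), 0, 0, 0)))
  expect_equal(tw2$moment,
               matrix(c(0, 0, J[3, 3] * alpha), n, 3, byrow = TRUE))
})

test_that("wrench transfer is involutive and preserves the force", {
  set.seed(4)
  t <- seq(0, 1, by = 0.01)
  w <- wrench_series(t, matrix(rnorm(3 * length(t)), ncol = 3),
                     matrix(rnorm(3 * length(t)), ncol = 3),
                     ref_point = c(0.3, -0.2, 0))
  expect_equal(transfer_wrench(w, c(0.3, -0.2, 0))$moment, w$moment)
  # pure force: moment gained is d x F
  d <- c(0.5, 0.1, 0)
  wf <- wrench_series(t, matrix(c(1, 2, 3), length(t), 3, byrow = TRUE),
                      ref_point = c(0, 0, 0))
  got <- transfer_wrench(wf, -d)$moment[1, ]
  expect_equal(got, c(d[2] * 3 - d[3] * 2, d[3] * 1 - d[1] * 3,
                      d[1] * 2 - d[2] * 1))
  # round trip
  back <- transfer_wrench(transfer_wrench(w, c(-1, 2, 0.5)), c(0.3, -0.2, 0))
  expect_lt(max(abs(back$moment - w$moment)), 1e-12)
  expect_equal(back$force, w$force)
  # the wrench screw (moment component along the force) is transfer-invariant
  moved <- transfer_wrench(w, c(10, -4, 2))
  along <- function(x) rowSums(x$moment * x$force) / sqrt(rowSums(x$force^2))
  expect_equal(along(moved), along(w), tolerance = 1e-10)
})

test_that("the external wrench is frame-covariant under fixed rotations", {
  pen <- make_pendulum(fs = 120, duration = 1)
  base <- total_external_moment(pen$body, pen$kin, ref_point = c(0, 0, 0))
  quat_mult <- function(q, r) c(
    q[1] * r[1] - sum(q[2:4] * r[2:4]),
    q[1] * r[2:4] + r[1] * q[2:4] + c(
      q[3] * r[4] - q[4] * r[3], q[4] * r[2] - q[2] * r[4],
      q[2] * r[3] - q[3] * r[2]))
  set.seed(5)
  for (rep in 1:3) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); ang <- runif(1, 0, pi)
    qQ <- c(cos(ang / 2), sin(ang / 2) * ax)
    Q <- gaitwrench:::quat_to_matrix(qQ)
    kin2 <- pen$kin
    # rotating the world rotates gravity too; keep gravity fixed by
    # rotating the body gravity vector instead
    body2 <- pen$body
    body2$gravity <- as.numeric(Q %*% pen$body$gravity)
    for (nm in names(kin2$segments)) {
      s <- kin2$segments[[nm]]
      kin2$segments[[nm]]$pos <- s$pos %*% t(Q)
      kin2$segments[[nm]]$acc <- s$acc %*% t(Q)
      kin2$segments[[nm]]$angvel <- s$angvel %*% t(Q)
      kin2$segments[[nm]]$angacc <- s$angacc %*% t(Q)
      kin2$segments[[nm]]$quat <- t(apply(s$quat, 1, function(q) quat_mult(qQ, q)))
    }
    rot <- total_external_moment(body2, kin2, ref_point = c(0, 0, 0))
    expect_equal(rot$force, base$force %*% t(Q), tolerance = 1e-8)
    expect_equal(rot$moment, base$moment %*% t(Q), tolerance = 1e-8)
  }
})
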