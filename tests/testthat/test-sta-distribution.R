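test_that("STA curves satisfy the endpoint invariants and match their
           analytic form", {
  sta <- sta_default()
  expect_equal(as.numeric(evaluate_sta(sta, 0)), rep(1, 6))
  expect_equal(as.numeric(evaluate_sta(sta, 1)), rep(0, 6))
  expect_error(evaluate_sta(sta, 1.2), "outside")
  expect_error(evaluate_sta(sta, -0.1), "outside")
  # dual implementation: spline tabulation vs the generating raised cosine
  tau <- seq(0, 1, 0.01)
  analytic <- (1 + cos(pi * tau)) / 2
  expect_equal(max(abs(evaluate_sta(sta, tau)[, 3] - analytic)), 0,
               tolerance = 1e-3)
  expect_equal(evaluate_sta(sta, 0.5)[1, ], rep(0.5, 6) |>
                 stats::setNames(colnames(evaluate_sta(sta, 0.5))),
               tolerance = 1e-6)
  # endpoint construction is validated
  expect_error(sta_function(c(0, 1), matrix(c(0.9, 0), 2, 6)), "endpoint")
})

test_that("distribution conserves the total wrench at machine precision and
           is continuous at the phase boundaries", {
  for (key in c("default", "noisy")) {
    tr <- cached_trial(key)
    pred <- run_predict(tr$kinematics, tr$body, filter = FALSE)
    FT <- pred$total$force
    expect_lt(max(abs(pred$left$force + pred$right$force - FT)), 1e-9)
    m_common <- function(w) transfer_wrench(w, c(0, 0, 0))$moment
    expect_lt(max(abs(m_common(pred$left) + m_common(pred$right) -
                        pred$total$moment)), 1e-9)
    # trailing foot force vanishes at its toe-off sample
    to <- pred$events[pred$events$event == "toe_off", ]
    for (k in seq_len(nrow(to))) {
      w <- if (to$foot[k] == "left") pred$left else pred$right
      expect_equal(max(abs(w$force[to$index[k], ])), 0)
    }
    # continuity at contralateral heel strike: f(0) = 1 keeps the trailing
    # force continuous across the single-to-double support boundary
    hs <- pred$events[pred$events$event == "heel_strike", ]
    for (k in seq_len(nrow(hs))) {
      i <- hs$index[k]
      if (i < 3) next
      other <- if (hs$foot[k] == "left") pred$right else pred$left
      jump <- abs(other$force[i, ] - other$force[i - 1, ])
      step <- abs(other$force[i - 1, ] - other$force[i - 2, ])
      expect_lt(max(jump), max(step) * 3 + 1e-6)
    }
  }
})

test_that("a trial generated with the same STA curves is recovered exactly
           per foot", {
  tr <- cached_trial()
  pred <- run_predict(tr$kinematics, tr$body, filter = FALSE)
  bw <- tr$body$total_mass * 9.81
  expect_lt(max(abs(pred$left$force - tr$truth$left$force)) / bw, 1e-6)
  expect_lt(max(abs(pred$right$force - tr$truth$right$force)) / bw, 1e-6)
  expect_lt(max(abs(pred$left$moment - tr$truth$left$moment)), 1e-6)
  expect_lt(max(abs(pred$right$moment - tr$truth$right$moment)), 1e-6)
})

test_that("monotone vertical STA curve yields monotone trailing vertical
           force under a constant total force", {
  fx <- linear_ds_fixture()
  n <- length(fx$time)
  total <- wrench_series(fx$time, matrix(c(0, 0, 700), n, 3, byrow = TRUE),
                         matrix(0, n, 3), frame = "walking")
  ankle0 <- matrix(0, n, 3)
  dist <- distribute_wrench(total, fx$events, sta_default(),
                            ankle_l = cbind(0.2, 0.1, 0) [rep(1, n), ],
                            ankle_r = cbind(-0.2, -0.1, 0) [rep(1, n), ])
  ds <- fx$hs_l:(fx$to_r - 1)
  expect_true(all(diff(dist$right$force[ds, 3]) <= 1e-12))
})

test_that("calibration recovers a linear decay and is idempotent under
           duplicated episodes", {
  fx <- linear_ds_fixture()
  cal <- calibrate_sta(fx$left, fx$right, fx$events, fx$time)
  expect_equal(attr(cal, "n_episodes"), 1L)
  # knots reproduce f(tau) = 1 - tau
  expect_equal(cal$values[, 1], 1 - cal$tau, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(cal$values[, 6], 1 - cal$tau, tolerance = 1e-9,
               ignore_attr = TRUE)
  # duplicated identical episode: same mean curve
  n <- length(fx$time)
  t2 <- c(fx$time, fx$time + fx$time[n] + diff(fx$time)[1])
  dup <- function(w) wrench_series(t2, rbind(w$force, w$force),
                                   rbind(w$moment, w$moment), frame = "walking")
  ev2 <- structure(
    data.frame(foot = rep(c("left", "right"), 2),
               event = rep(c("heel_strike", "toe_off"), 2),
               time = t2[c(fx$hs_l, fx$to_r, fx$hs_l + n, fx$to_r + n)],
               index = c(fx$hs_l, fx$to_r, fx$hs_l + n, fx$to_r + n)),
    class = c("gait_events", "data.frame"),
    initial_state = c(left = "swing", right = "stance"))
  # close the left foot's first stance and reopen the right foot's stance
  # just before the duplicated episode, so exactly two double-support
  # episodes exist, both with the right foot trailing
  ev2 <- rbind(ev2, data.frame(foot = c("left", "right"),
                               event = c("toe_off", "heel_strike"),
                               time = t2[c(fx$hs_l + n - 2, fx$hs_l + n - 1)],
                               index = c(fx$hs_l + n - 2L, fx$hs_l + n - 1L)))
  ev2 <- structure(ev2[order(ev2$index), ],
                   class = c("gait_events", "data.frame"),
                   initial_state = c(left = "swing", right = "stance"))
  cal2 <- calibrate_sta(dup(fx$left), dup(fx$right), ev2, t2)
  expect_equal(attr(cal2, "n_episodes"), 2L)
  expect_equal(cal2$values, cal$values, tolerance = 1e-9)
})

test_that("degenerate double-support intervals are rejected", {
  t <- (0:99) / 100
  ev <- structure(
    data.frame(foot = c("left", "right"), event = c("heel_strike", "toe_off"),
               time = c(t[50], t[50]), index = c(50L, 50L)),
    class = c("gait_events", "data.frame"),
    initial_state = c(left = "swing", right = "stance"))
  total <- wrench_series(t, matrix(c(0, 0, 700), 100, 3, byrow = TRUE),
                         matrix(0, 100, 3), frame = "walking")
  z <- matrix(0, 100, 3)
  # a zero-length overlap produces no double-support episode at all:
  # distribution degenerates to pure single support, which is permitted
  expect_no_error(distribute_wrench(total, ev, sta_default(), z, z))
})
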