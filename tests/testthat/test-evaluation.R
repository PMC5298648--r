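# periodic grid on which sin(2 pi t) attains +/-1 exactly, so peak-to-peak
# ranges are exactly 2
grid_t <- (0:999) / 1000

test_that("RMSE and relative RMSE match closed forms", {
  s <- sin(2 * pi * grid_t)
  expect_equal(rmse_rrmse(s, s), list(rmse = 0, rrmse_percent = 0))
  # constant 0.1 offset on a unit sine: both ranges 2, rrmse = 5%
  r <- rmse_rrmse(s + 0.1, s)
  expect_equal(r$rmse, 0.1, tolerance = 1e-9)
  expect_equal(r$rrmse_percent, 5.0, tolerance = 1e-9)
  # sign flip of a zero-mean curve: the pointwise difference is 2s,
  # so rmse = 2 * rms
  r2 <- rmse_rrmse(-s, s)
  expect_equal(r2$rmse, 2 * sqrt(mean(s^2)), tolerance = 1e-12)
  expect_warning(rmse_rrmse(rep(1, 5), rep(1, 5)), "zero range")
  # invariant under common affine rescaling
  a <- 3.7; b <- -2.2
  r3 <- rmse_rrmse(a * (s + 0.1) + b, a * s + b)
  expect_equal(r3$rrmse_percent, r$rrmse_percent, tolerance = 1e-9)
})

test_that("correlation categories follow the published bands exactly", {
  expect_equal(correlation_category(0.992), "excellent")
  expect_equal(correlation_category(0.862), "strong")
  expect_equal(correlation_category(0.35), "weak")       # boundary inclusive
  expect_equal(correlation_category(0.350001), "moderate")
  expect_equal(correlation_category(0.67), "moderate")
  expect_equal(correlation_category(0.9), "strong")
  expect_equal(correlation_category(0.900001), "excellent")
  expect_equal(correlation_category(-0.2), "weak")
  p <- pearson_with_category(grid_t, 2 * grid_t + 1)
  expect_equal(p$rho, 1)
  expect_equal(p$category, "excellent")
  expect_warning(pearson_with_category(rep(1, 5), 1:5), "constant")
})

test_that("Sprague-Geers magnitude and phase match closed forms", {
  # exact discrete orthogonality: full periods on a uniform periodic grid
  n <- 1200
  x <- 2 * pi * (0:(n - 1)) / n
  m <- sin(3 * x)
  expect_equal(sprague_geers(m, m), list(M_percent = 0, P_percent = 0))
  sg <- sprague_geers(1.1 * m, m)
  expect_equal(sg$M_percent, 10.0, tolerance = 1e-9)
  expect_equal(sg$P_percent, 0, tolerance = 1e-9)
  # quarter-period shift of a pure sine: M = 0, P = 50
  sg2 <- sprague_geers(cos(3 * x), m)
  expect_equal(sg2$M_percent, 0, tolerance = 1e-9)
  expect_equal(sg2$P_percent, 50.0, tolerance = 1e-9)
  # P is symmetric in its arguments
  set.seed(6)
  a <- sin(x) + 0.3 * rnorm(n); b <- sin(x + 0.4)
  expect_equal(sprague_geers(a, b)$P_percent, sprague_geers(b, a)$P_percent)
  # M depends only on the amplitude ratio for proportional curves
  expect_equal(sprague_geers(0.8 * b, b)$M_percent, -20, tolerance = 1e-9)
  expect_error(sprague_geers(rep(0, 5), rep(1, 5)), "zero-energy")
})

test_that("sub-phase metrics isolate where the error lives", {
  n <- 300
  phase <- rep(c("DS1", "SS", "DS2"), each = 100)
  meas <- sin(2 * pi * (1:n) / n)
  pred <- meas
  pred[phase == "DS2"] <- pred[phase == "DS2"] + 0.2
  sm <- subphase_metrics(pred, meas, phase)
  expect_equal(sm$rmse[sm$phase == "DS1"], 0)
  expect_equal(sm$rmse[sm$phase == "SS"], 0)
  expect_gt(sm$rmse[sm$phase == "DS2"], 0.19)
  # identical curves: all slices zero
  sm0 <- subphase_metrics(meas, meas, phase)
  expect_equal(sm0$rmse, rep(0, 3))
  expect_warning(expect_warning(subphase_metrics(pred, meas, rep("SS", n)),
                                "DS1 empty"), "DS2 empty")
})

test_that("peak analysis locates the named stance extrema", {
  n <- 99
  frac <- (1:n) / n
  curves <- matrix(0, n, 6)
  # double-peak vertical profile with a mid-stance valley
  curves[, 3] <- 1 + 0.15 * sin(2 * pi * frac) - 0.25 * sin(pi * frac)^8
  curves[, 1] <- -0.2 * sin(pi * pmin(frac / 0.33, 1)) +
    0.25 * sin(pi * pmax((frac - 0.66) / 0.34, 0))
  curves[, 2] <- 0.05 * sin(pi * frac)
  pk <- peak_analysis(curves, curves)
  expect_equal(pk$abs_diff, rep(0, nrow(pk)))
  expect_equal(pk$measured[pk$name == "vertical_GRF_min_MS"],
               min(curves[34:66, 3]))
  expect_equal(pk$measured[pk$name == "anterior_GRF_min_ES"],
               min(curves[1:33, 1]))
  # constant vertical offset propagates into every vertical peak
  shifted <- curves; shifted[, 3] <- shifted[, 3] + 0.01
  pk2 <- peak_analysis(shifted, curves)
  vrows <- grepl("vertical", pk2$name)
  expect_equal(pk2$abs_diff[vrows], rep(0.01, sum(vrows)), tolerance = 1e-12)
  expect_error(peak_analysis(curves[0, , drop = FALSE], curves[0, , drop = FALSE]),
               "empty")
})
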