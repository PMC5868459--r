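make_curve <- function(values, n_bins = 64, occupancy = 40, n_trials = 160) {
  structure(list(centers = -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins,
                 mean_bias = values, occupancy = occupancy,
                 n_trials = n_trials),
            class = "bias_curve")
}

test_that("relative orientation follows the clockwise-negative convention", {
  expect_equal(relative_orientation(1.3, 1.3), 0)
  expect_equal(rad2deg(relative_orientation(deg2rad(10), deg2rad(30))), -20)
  set.seed(71)
  a <- runif(100, -3, 3); b <- runif(100, -3, 3)
  expect_equal(relative_orientation(a, b), -relative_orientation(b, a),
               tolerance = 1e-12)
})

test_that("sliding bins have the documented geometry", {
  set.seed(72)
  d <- runif(160, -pi, pi); e <- rnorm(160, 0, 0.2)
  cv <- sliding_bin_bias(d, e)
  expect_length(cv$centers, 64)
  expect_equal(cv$occupancy, 40)           # a quarter of 160 trials
  expect_equal(diff(cv$centers), rep(2 * pi / 64, 63))
  expect_true(all(cv$centers > -pi & cv$centers <= pi))
  expect_equal(sum(cv$centers > 0), 32)    # half-step offset: 32/32 split
  expect_false(any(cv$centers == 0))
  cv2 <- sliding_bin_bias(runif(10, -pi, pi), rnorm(10))
  expect_equal(cv2$occupancy, 2)           # floor of max(2, round(n/4))
  expect_error(sliding_bin_bias(d[1:5], e[1:5]), "at least 8")
  expect_error(sliding_bin_bias(d, e[-1]), "paired")
})

test_that("a constant error field yields a flat curve at that constant", {
  d <- runif(200, -pi, pi)
  cv <- sliding_bin_bias(d, rep(deg2rad(5), 200))
  expect_equal(cv$mean_bias, rep(deg2rad(5), 64))
})

test_that("an injected sinusoidal bias is recovered by harmonic regression", {
  set.seed(73)
  beta <- deg2rad(-5)
  d <- runif(2000, -pi, pi)
  e <- beta * sin(d) + rvonmises(2000, 0, 50)
  cv <- sliding_bin_bias(d, e)
  h <- lm(cv$mean_bias ~ sin(cv$centers) + cos(cv$centers))
  amp <- coef(h)[["sin(cv$centers)"]]
  expect_lt(abs(amp - beta), deg2rad(1))
  expect_lt(amp, 0)
})

test_that("area difference matches the closed-form value on exact harmonics", {
  centers <- -pi + (1:64 - 0.5) * 2 * pi / 64
  # discrete oracle: mean of sin over the positive half minus negative half
  oracle <- mean(sin(centers[centers > 0])) - mean(sin(centers[centers < 0]))
  expect_equal(oracle, 4 / pi, tolerance = 1e-3)   # midpoint-rule integral
  ad <- area_difference(make_curve(sin(centers)))
  expect_equal(ad$area_diff, oracle)
  expect_equal(ad$direction, "attraction")
  neg <- area_difference(make_curve(-sin(centers)))
  expect_equal(neg$area_diff, -ad$area_diff)
  expect_equal(neg$direction, "repulsion")
  expect_equal(area_difference(make_curve(rep(0.3, 64)))$area_diff, 0)
})

test_that("bias curves are shift equivariant and reflection antisymmetric", {
  set.seed(74)
  d <- runif(300, -pi, pi); e <- rnorm(300, 0, 0.3)
  cv <- sliding_bin_bias(d, e)
  shifted <- sliding_bin_bias(d, e + 0.17)
  expect_equal(shifted$mean_bias, cv$mean_bias + 0.17, tolerance = 1e-12)
  expect_equal(area_difference(shifted)$area_diff,
               area_difference(cv)$area_diff, tolerance = 1e-12)
  # jointly negating deltas and errors mirrors the curve about the origin:
  # the bin at centre c now holds the former bin at -c with flipped sign,
  # so the area difference (an odd functional of an odd transformation) is
  # unchanged
  mirrored <- sliding_bin_bias(-d, -e)
  expect_equal(mirrored$mean_bias, -rev(cv$mean_bias), tolerance = 1e-12)
  expect_equal(area_difference(mirrored)$area_diff,
               area_difference(cv)$area_diff, tolerance = 1e-12)
  # negating the errors alone flips attraction into repulsion
  flipped <- sliding_bin_bias(d, -e)
  expect_equal(area_difference(flipped)$area_diff,
               -area_difference(cv)$area_diff, tolerance = 1e-12)
})

test_that("the group bias test behaves at its edges", {
  res <- bias_group_test(rep(0, 10))
  expect_equal(res$statistic, 0)
  expect_error(bias_group_test(c(0.1, 0.2)), "at least 3")
})

test_that("the sign of a generated sinusoidal bias is recovered in expectation", {
  set.seed(75)
  mean_ad <- function(beta) {
    ads <- replicate(20, {
      d <- runif(400, -pi, pi)
      e <- beta * sin(d) + rvonmises(400, 0, 12)
      area_difference(sliding_bin_bias(d, e))$area_diff
    })
    mean(ads)
  }
  expect_lt(mean_ad(deg2rad(-5)), 0)
  expect_gt(mean_ad(deg2rad(5)), 0)
  expect_lt(abs(mean_ad(0)), deg2rad(1.5))
})
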