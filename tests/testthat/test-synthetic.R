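test_that("design presets reproduce the experiments' trial structure", {
  e1 <- design_spec("E1")
  expect_equal(e1$n_blocks * e1$trials_per_block, 480)
  expect_equal(unname(e1$condition_mix), c(20, 20, 20))
  expect_false(any(e1$order_cued))
  e3 <- design_spec("E3")
  expect_equal(e3$n_blocks * e3$trials_per_block, 600)
  expect_equal(sum(e3$order_cued), 5)
  expect_error(design_spec("E1", condition_mix = c(neutral = 10,
    cued_first = 10, cued_second = 10)), "sum to trials_per_block")
})

test_that("simulated sessions respect the design counts and invariants", {
  co <- simulate_session(design_spec("E1"), generative_params(), seed = 101)
  d <- as.data.frame(co)
  expect_equal(nrow(d), 480)
  expect_equal(as.integer(table(d$condition)), rep(160L, 3))
  expect_equal(as.integer(table(d$block)), rep(60L, 8))
  # invariants are enforced at construction; spot-check the cue linkage
  cf <- d[d$condition == "cued_first", ]
  expect_equal(cf$probe1_item, cf$cued_item)
  cs <- d[d$condition == "cued_second", ]
  expect_equal(cs$probe2_item, cs$cued_item)
  expect_true(all(is.na(d$cued_item[d$condition == "neutral"])))
  expect_true(all(d$probe1_item != d$probe2_item))
})

test_that("simulation is bit-reproducible from the seed", {
  p <- generative_params()
  a <- simulate_cohort(small_e1(), p, 3, seed = 102)
  b <- simulate_cohort(small_e1(), p, 3, seed = 102)
  expect_identical(a, b)
  c2 <- simulate_cohort(small_e1(), p, 3, seed = 103)
  expect_false(identical(a, c2))
})

test_that("the noiseless limit produces near-perfect responses", {
  p <- generative_params(p_mem = 1, kappa = 5000, beta = 0,
                         subject_sd = list(p_mem = 0, kappa = 0, beta = 0))
  co <- simulate_session(small_e1(), p, seed = 104)
  errs <- response_errors(co)
  expect_lt(max(abs(rad2deg(errs$error))), 5)
})

test_that("generated errors match the mixture distribution they came from", {
  p <- generative_params(p_mem = 0.7, kappa = 10,
                         subject_sd = list(p_mem = 0, kappa = 0, beta = 0))
  co <- simulate_session(design_spec("E1"), p, seed = 105)
  errs <- response_errors(co)
  mix_cdf <- function(q) vapply(q, function(x)
    integrate(function(u)
      0.7 * exp(10 * cos(u)) / (2 * pi * besselI(10, 0)) + 0.3 / (2 * pi),
      -pi, x, rel.tol = 1e-8)$value, numeric(1))
  ks <- suppressWarnings(ks.test(errs$error, mix_cdf))
  expect_gt(ks$p.value, 0.01)
  # and the mixture fit recovers the truth
  fit <- fit_mixture(errs$error)
  expect_lt(abs(fit$p_mem - 0.7), 0.05)
  expect_lt(abs(fit$kappa - 10) / 10, 0.2)
})

test_that("per-subject parameter perturbation stays within bounds", {
  p <- generative_params(p_mem = 0.95, kappa = 3,
                         subject_sd = list(p_mem = 0.2, kappa = 3,
                                           beta = 0))
  co <- simulate_cohort(small_e1(), p, 12, seed = 106)
  # recall rates are probabilities: fits must stay in [0, 1] even though
  # the cohort mean sits near the boundary
  errs <- response_errors(co)
  fits <- mixture_table(errs[errs$role == "cued" &
                               errs$response_index == 1, ])
  expect_true(all(fits$p_mem >= 0 & fits$p_mem <= 1))
  expect_true(all(fits$kappa >= 0))
})

test_that("an injected repulsive bias propagates to the area statistic", {
  des <- one_condition_design("cued_second", 160)
  co <- simulate_cohort(des, params_repulsion(), 24, seed = 107)
  errs <- response_errors(co)
  e1 <- errs[errs$response_index == 1, ]   # uncued item recalled first
  ads <- vapply(split(e1, e1$subject_id), function(d)
    area_difference(sliding_bin_bias(d$delta, d$error))$area_diff,
    numeric(1))
  expect_lt(mean(ads), 0)
  expect_lt(bias_group_test(ads)$p, 0.05)
})

test_that("minimum item separation is honoured when requested", {
  des <- design_spec("E1", n_blocks = 1, min_separation = 20)
  co <- simulate_session(des, generative_params(), seed = 108)
  d <- as.data.frame(co)
  items <- as.matrix(d[c("item1_deg", "item2_deg", "item3_deg",
                         "item4_deg")])
  for (i in seq_len(nrow(items))) {
    diffs <- abs(rad2deg(wrap_angle(deg2rad(outer(items[i, ], items[i, ],
                                                  "-")))))
    expect_gte(min(diffs[upper.tri(diffs)]), 20)
  }
})
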