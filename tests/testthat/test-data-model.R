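make_trials <- function(...) {
  base <- data.frame(
    subject_id = "s01", experiment = "E1", block = 1L, trial = 1:2,
    condition = c("neutral", "cued_first"), order_cued = FALSE,
    item1_deg = c(10, 20), item2_deg = c(100, 110),
    item3_deg = c(200, 210), item4_deg = c(300, 310),
    cued_item = c(NA, 2L), probe1_item = c(1L, 2L), probe2_item = c(3L, 4L),
    response1_deg = c(12, 108), response2_deg = c(205, NA),
    rt1_ms = c(900, 1100), rt2_ms = c(1200, NA),
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("a small valid CSV round-trips identically", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- trial_cohort(make_trials())
  write_trials(co, path)
  back <- read_trials(path)
  expect_s3_class(back, "trial_cohort")
  expect_equal(nrow(back), 2)
  expect_equal(length(unique(back$subject_id)), 1)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-9)
  expect_true(is.na(back$response2_deg[2]))   # empty field read as missing
})

test_that("simulated sessions survive a write/read round trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- simulate_cohort(small_e1(), generative_params(), 2, seed = 9)
  write_trials(co, path)
  back <- read_trials(path)
  num <- vapply(as.data.frame(co), is.numeric, logical(1))
  for (col in names(co)[num])
    expect_equal(back[[col]], co[[col]], tolerance = 1e-6, label = col)
  for (col in names(co)[!num])
    expect_identical(back[[col]], co[[col]], label = col)
})

test_that("schema and invariant violations are rejected with diagnostics", {
  expect_error(trial_cohort(make_trials(probe2_item = c(1L, 2L))),
               "probe1_item equals probe2_item.*row")
  expect_error(trial_cohort(make_trials(item1_deg = c(-5, 20))),
               "item1_deg.*row\\(s\\): 1")
  expect_error(trial_cohort(make_trials(response1_deg = c(400, 108))),
               "response1_deg")
  expect_error(trial_cohort(make_trials(cued_item = c(3L, 2L))),
               "neutral")
  expect_error(trial_cohort(make_trials(condition = c("neutral", "odd"))),
               "condition")
  expect_error(trial_cohort(make_trials(cued_item = c(NA, 4L))),
               "cued_first")
  expect_error(trial_cohort(make_trials()[-3]), "missing mandatory")
  extra <- make_trials(); extra$junk <- 1
  expect_warning(co <- trial_cohort(extra), "ignoring extra")
  expect_false("junk" %in% names(co))
})

test_that("writing an empty cohort yields a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trial_cohort(make_trials()[0, ]), path)
  lines <- readLines(path)
  expect_equal(length(lines), 1)
  expect_match(lines, "^subject_id,experiment,block,trial,condition")
})

test_that("label_responses assigns exactly one cued role per cued trial", {
  r <- label_responses(c("neutral", "cued_first", "cued_second"))
  expect_equal(r$role1, c("neutral", "cued", "uncued"))
  expect_equal(r$role2, c("neutral", "uncued", "cued"))
  n_cued <- (r$role1 == "cued") + (r$role2 == "cued")
  expect_equal(n_cued, c(0L, 1L, 1L))
  expect_error(label_responses("bogus"), "unknown condition")
})

test_that("exclusion keeps precise responders and drops uniform guessers", {
  des <- small_e1()
  good <- simulate_session(des, generative_params(), seed = 2,
                           subject_id = "good")
  guesser <- simulate_session(des,
    generative_params(p_mem = 0, kappa = 1), seed = 3,
    subject_id = "guesser")
  co <- rbind(as.data.frame(good), as.data.frame(guesser))
  class(co) <- c("trial_cohort", "data.frame")
  out <- exclude_participants(co)
  expect_equal(out$report$excluded[out$report$subject_id == "guesser"], TRUE)
  expect_equal(out$report$excluded[out$report$subject_id == "good"], FALSE)
  expect_equal(unique(out$retained$subject_id), "good")
  expect_true(all(c("rayleigh_z", "p") %in% names(out$report)))

  # invariant to trial ordering
  set.seed(7)
  shuffled <- co[sample(nrow(co)), ]
  class(shuffled) <- c("trial_cohort", "data.frame")
  out2 <- exclude_participants(shuffled)
  expect_equal(out2$report[order(out2$report$subject_id), ],
               out$report[order(out$report$subject_id), ],
               ignore_attr = TRUE)
})

test_that("typical memory-driven cohorts yield no exclusions", {
  p <- generative_params(p_mem = 0.7, kappa = 10,
                         subject_sd = list(p_mem = 0, kappa = 0, beta = 0))
  for (seed in 1:3) {
    co <- simulate_cohort(small_e1(), p, 4, seed = seed)
    expect_equal(sum(exclude_participants(co)$report$excluded), 0)
  }
})

test_that("exclusion refuses subjects with too few responses", {
  co <- trial_cohort(make_trials())
  expect_error(exclude_participants(co), "fewer than 10")
})
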