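# Synthetic trial generator emulating the four double-probe retrocueing
# designs. Item orientations are uniform on the circle; each response is a
# draw from the two-component mixture (target-centred von Mises with
# probability p_mem, uniform guess otherwise), with an optional
# orientation-dependent bias of the recalled component and optional
# trial-wise coupling of the two responses' precision.

#' Design specification for one experiment
#'
#' Presets mirror the four designs: E1 (8 blocks x 60 trials, 20 neutral /
#' 20 cued-first / 20 cued-second per block, order never cued, 480 trials);
#' E2 (as E1 but the cue also conveys probe order); E2b (as E2, order cue
#' blocked); E3 (two sessions, order cued in one, 100 trials per condition
#' per session: 10 blocks x 60 trials, 600 in total).
#'
#' @param experiment `"E1"`, `"E2"`, `"E2b"`, or `"E3"`.
#' @param n_blocks,trials_per_block Override the preset block structure.
#' @param condition_mix Named integer vector of per-block trial counts for
#'   `neutral`, `cued_first`, `cued_second`; must sum to `trials_per_block`.
#' @param order_cued Logical, one value per block (recycled), whether the
#'   cue also conveys probe order in that block.
#' @param min_separation Minimum angular separation between the four item
#'   orientations, in degrees (default 0: draw independently).
#' @return Object of class `design_spec`.
#' @examples
#' design_spec("E1")
#' @export
design_spec <- function(experiment = c("E1", "E2", "E2b", "E3"),
                        n_blocks = NULL, trials_per_block = NULL,
                        condition_mix = NULL, order_cued = NULL,
                        min_separation = 0) {
  experiment <- match.arg(experiment)
  preset <- switch(experiment,
    E1  = list(blocks = 8L,  per = 60L, order = FALSE),
    E2  = list(blocks = 8L,  per = 60L, order = TRUE),
    E2b = list(blocks = 8L,  per = 60L, order = TRUE),
    E3  = list(blocks = 10L, per = 60L,
               order = rep(c(FALSE, TRUE), each = 5L)))
  n_blocks <- if (is.null(n_blocks)) preset$blocks else as.integer(n_blocks)
  trials_per_block <- if (is.null(trials_per_block)) preset$per
                      else as.integer(trials_per_block)
  if (is.null(condition_mix))
    condition_mix <- c(neutral = trials_per_block %/% 3L,
                       cued_first = trials_per_block %/% 3L,
                       cued_second = trials_per_block %/% 3L)
  if (!setequal(names(condition_mix), CONDITIONS))
    stop("design_spec: condition_mix must name ",
         paste(CONDITIONS, collapse = ", "))
  condition_mix <- condition_mix[CONDITIONS]
  if (sum(condition_mix) != trials_per_block)
    stop("design_spec: condition_mix must sum to trials_per_block")
  order_cued <- rep_len(if (is.null(order_cued)) preset$order else order_cued,
                        n_blocks)
  structure(
    list(experiment = experiment, n_blocks = n_blocks,
         trials_per_block = trials_per_block, condition_mix = condition_mix,
         order_cued = order_cued, n_items = 4L, probes_per_trial = 2L,
         min_separation = min_separation),
    class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "Design %s: %d blocks x %d trials (%s), %d trials total\n",
    x$experiment, x$n_blocks, x$trials_per_block,
    paste(sprintf("%s %d", names(x$condition_mix), x$condition_mix),
          collapse = ", "),
    x$n_blocks * x$trials_per_block))
  invisible(x)
}

role_matrix <- function(x, what) {
  roles <- c("cued", "uncued", "neutral")
  if (is.matrix(x)) {
    if (!all(roles %in% rownames(x)) || ncol(x) != 2)
      stop("generative_params: ", what,
           " matrix needs rows cued/uncued/neutral and 2 columns")
    return(x[roles, , drop = FALSE])
  }
  if (length(x) == 1) x <- rep(x, 6)
  matrix(x, nrow = 3, ncol = 2, dimnames = list(roles, c("1", "2")))
}

#' Generative parameters of the synthetic cohort
#'
#' Cohort-level truth for the response model, organised per cue role
#' (`cued`, `uncued`, `neutral`) and response index (1, 2). Defaults encode
#' the qualitative pattern the analyses are designed to detect: recall rate
#' highest for cued items and lowest for uncued ones, a small second-response
#' decrement, slightly higher precision for cued items probed first, and no
#' bias or coupling.
#'
#' @param p_mem Recall probability; scalar or 3 x 2 matrix
#'   (rows `cued`, `uncued`, `neutral`; columns response 1, 2).
#' @param kappa von Mises concentration, same shape.
#' @param beta Bias amplitude in radians, same shape. A recalled response
#'   with role r and index i has its von Mises component centred on
#'   `beta[r, i] * sin(delta)` where `delta` is the relative orientation of
#'   the other probed item w.r.t. the current target: negative beta pushes
#'   responses away from the other orientation (repulsion).
#' @param coupling `"independent"`, `"shared_gain"`, or
#'   `"resource_tradeoff"`: how the two responses' precision covaries within
#'   a trial. `shared_gain` multiplies both kappas by the same per-trial
#'   gain `2g` (positive |error| correlation); `resource_tradeoff` splits a
#'   fixed budget, `kappa1 = kappa * 2g`, `kappa2 = kappa * 2(1 - g)`
#'   (negative correlation), with `g ~ Beta(a, a)`.
#' @param coupling_strength In [0, 1): variance of the per-trial gain `g`
#'   as a fraction of its maximum 1/4; 0 collapses to independent.
#' @param subject_sd Named list of between-subject SDs for `p_mem`, `kappa`
#'   and `beta` (truncated-normal perturbations of the cohort means).
#' @return Object of class `generative_params`.
#' @export
generative_params <- function(
    p_mem = matrix(c(0.95, 0.80, 0.88,
                     0.90, 0.80, 0.82), nrow = 3,
                   dimnames = list(c("cued", "uncued", "neutral"), 1:2)),
    kappa = matrix(c(15, 12, 12,
                     12, 12, 12), nrow = 3,
                   dimnames = list(c("cued", "uncued", "neutral"), 1:2)),
    beta = 0,
    coupling = c("independent", "shared_gain", "resource_tradeoff"),
    coupling_strength = 0,
    subject_sd = list(p_mem = 0.05, kappa = 2, beta = deg2rad(1))) {
  coupling <- match.arg(coupling)
  p_mem <- role_matrix(p_mem, "p_mem")
  kappa <- role_matrix(kappa, "kappa")
  beta <- role_matrix(beta, "beta")
  if (any(p_mem < 0 | p_mem > 1)) stop("generative_params: p_mem in [0, 1]")
  if (any(kappa < 0)) stop("generative_params: kappa must be nonnegative")
  if (coupling_strength < 0 || coupling_strength >= 1)
    stop("generative_params: coupling_strength in [0, 1)")
  structure(
    list(p_mem = p_mem, kappa = kappa, beta = beta, coupling = coupling,
         coupling_strength = coupling_strength, subject_sd = subject_sd),
    class = "generative_params")
}

#' Parameters emulating the first experiment's findings
#'
#' [generative_params()] defaults plus a repulsive bias of `-5` degrees
#' (first circular harmonic) on the first response of cued-second trials,
#' where the recall of the not-yet-reported cued item distorts the response
#' to the uncued item.
#'
#' @param beta_repulsion Bias amplitude in radians for the (uncued, response
#'   1) cell; default `-5` degrees.
#' @param ... Passed on to [generative_params()].
#' @return Object of class `generative_params`.
#' @export
params_repulsion <- function(beta_repulsion = deg2rad(-5), ...) {
  p <- generative_params(...)
  p$beta["uncued", 1] <- beta_repulsion
  p
}

# truncated-normal perturbation of a role x index matrix
perturb <- function(m, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(m)
  out <- m + stats::rnorm(length(m), 0, sd)
  pmin(pmax(out, lo), hi)
}

draw_items <- function(n_trials, min_separation) {
  items <- matrix(stats::runif(n_trials * 4, 0, 360), ncol = 4)
  if (min_separation > 0) {
    ok <- function(row) {
      d <- abs(rad2deg(wrap_angle(deg2rad(outer(row, row, "-")))))
      all(d[upper.tri(d)] >= min_separation)
    }
    for (i in seq_len(n_trials))
      while (!ok(items[i, ])) items[i, ] <- stats::runif(4, 0, 360)
  }
  items
}

#' Simulate one subject's session
#'
#' Builds the full trial table for one subject under a design and a set of
#' generative parameters. Item orientations are uniform on [0, 360); cue
#' and probe assignments are uniform over the design's legal choices; each
#' response follows the two-component mixture with the role- and
#' index-specific parameters, an optional `beta * sin(delta)` bias of the
#' recalled component, and the configured precision coupling. Fully
#' reproducible from `seed`.
#'
#' @param design A `design_spec`.
#' @param params A `generative_params` (subject-level truth; no
#'   between-subject perturbation is applied here).
#' @param seed Integer seed.
#' @param subject_id Subject label (default `"s01"`).
#' @return A `trial_cohort` with one session.
#' @export
simulate_session <- function(design, params, seed, subject_id = "s01") {
  stopifnot(inherits(design, "design_spec"),
            inherits(params, "generative_params"))
  set.seed(seed)
  n <- design$n_blocks * design$trials_per_block
  condition <- unlist(lapply(seq_len(design$n_blocks), function(b)
    sample(rep(CONDITIONS, times = design$condition_mix))))
  items <- draw_items(n, design$min_separation)

  # cue and probe assignment, uniform over legal choices
  cued <- ifelse(condition == "neutral", NA_integer_,
                 sample.int(4L, n, replace = TRUE))
  other <- vapply(seq_len(n), function(i) {
    pool <- if (is.na(cued[i])) 1:4 else setdiff(1:4, cued[i])
    pool[sample.int(length(pool), 1L)]
  }, integer(1))
  second_neutral <- vapply(seq_len(n), function(i) {
    pool <- setdiff(1:4, other[i])
    pool[sample.int(3L, 1L)]
  }, integer(1))
  probe1 <- ifelse(condition == "cued_first", cued, other)
  probe2 <- ifelse(condition == "cued_first", other,
            ifelse(condition == "cued_second", cued, second_neutral))

  roles <- label_responses(condition)
  target1 <- deg2rad(items[cbind(seq_len(n), probe1)])
  target2 <- deg2rad(items[cbind(seq_len(n), probe2)])
  delta1 <- relative_orientation(target2, target1)
  delta2 <- relative_orientation(target1, target2)

  # per-trial precision coupling
  g <- if (params$coupling == "independent" || params$coupling_strength == 0)
    rep(0.5, n)
  else {
    a <- (1 / params$coupling_strength - 1) / 2
    stats::rbeta(n, a, a)
  }
  gain1 <- 2 * g
  gain2 <- switch(params$coupling,
                  independent = rep(1, n),
                  shared_gain = 2 * g,
                  resource_tradeoff = 2 * (1 - g))
  if (params$coupling == "independent") gain1 <- rep(1, n)

  respond <- function(idx, role, target, delta, gain) {
    pm <- params$p_mem[cbind(role, idx)]
    kp <- params$kappa[cbind(role, idx)] * gain
    bias <- params$beta[cbind(role, idx)] * sin(delta)
    recalled <- stats::runif(n) < pm
    err <- stats::runif(n, -pi, pi)
    if (any(recalled))
      err[recalled] <- rvm_each(kp[recalled]) + bias[recalled]
    wrap_angle(target + err)
  }
  resp1 <- respond("1", roles$role1, target1, delta1, gain1)
  resp2 <- respond("2", roles$role2, target2, delta2, gain2)

  trial_cohort(data.frame(
    subject_id = subject_id, experiment = design$experiment,
    block = rep(seq_len(design$n_blocks), each = design$trials_per_block),
    trial = unlist(lapply(seq_len(design$n_blocks),
                          function(b) seq_len(design$trials_per_block))),
    condition = condition,
    order_cued = rep(design$order_cued, each = design$trials_per_block),
    item1_deg = items[, 1], item2_deg = items[, 2],
    item3_deg = items[, 3], item4_deg = items[, 4],
    cued_item = cued, probe1_item = probe1, probe2_item = probe2,
    response1_deg = rad2deg(resp1) %% 360,
    response2_deg = rad2deg(resp2) %% 360,
    rt1_ms = NA_real_, rt2_ms = NA_real_,
    stringsAsFactors = FALSE))
}

#' Simulate a cohort of subjects
#'
#' Draws each subject's generative parameters from truncated normals around
#' the cohort means (`subject_sd` of `params`) and simulates every session
#' with an independent per-subject seed derived deterministically from the
#' master seed, so the same master seed reproduces the cohort bit for bit.
#'
#' @param design A `design_spec`.
#' @param params Cohort-level `generative_params`.
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Master integer seed.
#' @return A `trial_cohort` containing all subjects.
#' @export
simulate_cohort <- function(design, params, n_subjects, seed) {
  if (n_subjects < 1) stop("simulate_cohort: need n_subjects >= 1")
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  subject_param_list <- lapply(seq_len(n_subjects), function(i) {
    p <- params
    p$p_mem <- perturb(p$p_mem, params$subject_sd$p_mem, 0, 1)
    p$kappa <- perturb(p$kappa, params$subject_sd$kappa, 0.1, Inf)
    p$beta <- perturb(p$beta, params$subject_sd$beta)
    p
  })
  sessions <- lapply(seq_len(n_subjects), function(i)
    simulate_session(design, subject_param_list[[i]], subject_seeds[i],
                     subject_id = sprintf("s%02d", i)))
  out <- do.call(rbind, lapply(sessions, as.data.frame))
  class(out) <- c("trial_cohort", "data.frame")
  out
}
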