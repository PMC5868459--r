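# Trial-by-trial trade-off analysis: Pearson correlation between the
# absolute errors of the two sequential responses, Fisher z transform, and
# group-level inference. A zero-sum shared memory resource predicts
# negative correlations; independent storage predicts none.

#' Trial-wise correlation of absolute errors across the two responses
#'
#' Pearson correlation of |error 1| versus |error 2| across trials, with the
#' Fisher z transform (r clipped to +-(1 - 1e-12) so z stays finite).
#'
#' @param err1,err2 Paired signed errors in radians (absolute values are
#'   taken internally), length >= 10. Pairs with a missing member are
#'   dropped.
#' @param condition Optional condition label carried into the result.
#' @return Object of class `tradeoff_result`: list with `r`, `z`,
#'   `n_trials`, `condition`.
#' @export
trialwise_error_correlation <- function(err1, err2, condition = NA_character_) {
  if (length(err1) != length(err2))
    stop("trialwise_error_correlation: errors must be paired")
  keep <- !is.na(err1) & !is.na(err2)
  a <- abs(err1[keep]); b <- abs(err2[keep])
  if (length(a) < 10)
    stop("trialwise_error_correlation: need at least 10 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("trialwise_error_correlation: zero variance in absolute errors")
  r <- stats::cor(a, b)
  clip <- 1 - 1e-12
  z <- atanh(pmin(pmax(r, -clip), clip))
  structure(list(r = r, z = z, n_trials = length(a), condition = condition),
            class = "tradeoff_result")
}

#' @export
print.tradeoff_result <- function(x, ...) {
  cat(sprintf("Trade-off correlation%s: r = %+.3f (z = %+.3f, n = %d)\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$r, x$z, x$n_trials))
  invisible(x)
}

#' Group tests on Fisher-transformed trade-off correlations
#'
#' Per condition, a one-sample two-sided t test of the per-subject Fisher z
#' values against zero (with JZS Bayes factor); across conditions, a one-way
#' repeated-measures ANOVA for the main effect of cue condition.
#'
#' @param z_table Data frame with columns `subject_id`, `condition`, `z`;
#'   every subject must have every condition exactly once.
#' @return List with `per_condition` (an `inference_result` data frame, one
#'   row per condition) and `anova` (the RM-ANOVA `inference_result` table).
#' @export
tradeoff_group_test <- function(z_table) {
  req <- c("subject_id", "condition", "z")
  if (!all(req %in% names(z_table)))
    stop("tradeoff_group_test: need columns subject_id, condition, z")
  tab <- table(z_table$subject_id, z_table$condition)
  if (any(tab != 1))
    stop("tradeoff_group_test: unbalanced subject x condition table")
  per <- do.call(rbind, lapply(split(z_table, z_table$condition),
    function(d) one_sample_t(d$z, effect = paste0("z_", d$condition[1]))))
  rownames(per) <- NULL
  av <- rm_anova(z_table, dv = "z", subject = "subject_id",
                 factors = "condition")
  list(per_condition = per, anova = av)
}
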