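# Group-level inference: one-sample and paired t tests with Cohen's d and
# the default JZS Bayes factor, and fully within-subject repeated-measures
# ANOVA with partial eta squared. All results are returned as rows of a
# tidy `inference_result` data frame so they can be bound and exported
# directly.

inference_result <- function(effect, statistic, df1, df2 = NA_real_, p,
                             effect_size, bf10 = NA_real_) {
  structure(
    data.frame(effect = effect, statistic = statistic, df1 = df1, df2 = df2,
               p = p, effect_size = effect_size, bf10 = bf10,
               stringsAsFactors = FALSE),
    class = c("inference_result", "data.frame"))
}

#' One-sample t test with effect size and JZS Bayes factor
#'
#' Two-sided t test of `x` against `mu`, reporting Cohen's d
#' (`mean(x - mu) / sd(x)`) and the default JZS Bayes factor from
#' [jzs_bf_from_t()].
#'
#' @param x Numeric vector, length >= 3.
#' @param mu Null value (default 0).
#' @param effect Label for the result row.
#' @return An `inference_result` data frame with one row: `effect`,
#'   `statistic` (t), `df1` (n - 1), `df2` (NA), `p`, `effect_size`
#'   (Cohen's d), `bf10`.
#' @export
one_sample_t <- function(x, mu = 0, effect = "one_sample") {
  n <- length(x)
  if (n < 3) stop("one_sample_t: need at least 3 values")
  s <- stats::sd(x)
  if (s == 0) {
    if (mean(x) != mu) stop("one_sample_t: zero variance away from mu")
    return(inference_result(effect, 0, n - 1, NA_real_, 1, 0,
                            jzs_bf_from_t(0, n)))
  }
  t <- (mean(x) - mu) / (s / sqrt(n))
  inference_result(effect, t, n - 1, NA_real_,
                   2 * stats::pt(-abs(t), n - 1),
                   (mean(x) - mu) / s, jzs_bf_from_t(t, n))
}

#' Paired t test with effect size and JZS Bayes factor
#'
#' Two-sided paired t test on `a - b`; equivalent to [one_sample_t()] on
#' the differences.
#'
#' @param a,b Paired numeric vectors of equal length >= 3.
#' @param effect Label for the result row.
#' @return An `inference_result` data frame row.
#' @export
paired_t <- function(a, b, effect = "paired") {
  if (length(a) != length(b)) stop("paired_t: unequal lengths")
  one_sample_t(a - b, mu = 0, effect = effect)
}

#' Two-sample t test (pooled variance)
#'
#' Classical independent-samples t test with pooled variance, used for
#' between-experiment comparisons. No Bayes factor is attached.
#'
#' @param a,b Numeric vectors, each length >= 2.
#' @param effect Label for the result row.
#' @return An `inference_result` data frame row.
#' @export
two_sample_t <- function(a, b, effect = "two_sample") {
  ht <- stats::t.test(a, b, var.equal = TRUE)
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
              (length(b) - 1) * stats::var(b)) /
             (length(a) + length(b) - 2))
  inference_result(effect, unname(ht$statistic), unname(ht$parameter),
                   NA_real_, ht$p.value, (mean(a) - mean(b)) / sp)
}

#' Default JZS Bayes factor for a one-sample or paired t test
#'
#' Jeffreys-Zellner-Siow Bayes factor BF10 (alternative over null) for a
#' one-sample or paired design, computed by numerical quadrature over the
#' Cauchy prior on the standardised effect size (Rouder et al., 2009). The
#' default prior scale `sqrt(2)/2` matches the default of the BayesFactor
#' software. Depends only on |t| and n.
#'
#' @param t Observed t statistic.
#' @param n Sample size (pairs for a paired design), >= 3.
#' @param scale Cauchy prior scale on the effect size (default `sqrt(2)/2`).
#' @return Scalar BF10 (positive).
#' @examples
#' jzs_bf_from_t(2.74, 24)
#' @export
jzs_bf_from_t <- function(t, n, scale = sqrt(2) / 2) {
  if (!is.finite(t)) stop("jzs_bf_from_t: t must be finite")
  if (n < 3) stop("jzs_bf_from_t: need n >= 3")
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    lg <- -0.5 * log1p(n * g * scale^2) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g * scale^2) * nu)) -
      0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g)
    exp(lg - log_null)
  }
  q <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-8, abs.tol = 0,
                     subdivisions = 500L),
    error = function(e) stop("jzs_bf_from_t: quadrature failed: ",
                             conditionMessage(e)))
  q$value
}

#' Repeated-measures ANOVA with partial eta squared
#'
#' Fully within-subject ANOVA for up to three fully crossed factors on a
#' balanced long-format table. Each effect is tested against its own
#' effect-by-subject interaction (`F = MS_effect / MS_(effect x subject)`),
#' the classical univariate approach; no sphericity correction is applied.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`. Model
#' fitting is delegated to [stats::aov()] with an
#' `Error(subject/(f1*f2*...))` stratum structure.
#'
#' @param data Long data frame.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param factors Character vector of 1-3 within-subject factor columns.
#' @return An `inference_result` data frame, one row per main effect and
#'   interaction: `statistic` (F), `df1`, `df2`, `p`, `effect_size`
#'   (partial eta squared). `bf10` is NA (Bayesian ANOVA is out of scope).
#' @export
rm_anova <- function(data, dv, subject, factors) {
  if (length(factors) < 1 || length(factors) > 3)
    stop("rm_anova: need 1 to 3 within-subject factors")
  need <- c(dv, subject, factors)
  if (!all(need %in% names(data)))
    stop("rm_anova: missing column(s): ",
         paste(setdiff(need, names(data)), collapse = ", "))
  d <- data.frame(.y = data[[dv]], .subj = factor(data[[subject]]))
  for (f in factors) d[[f]] <- factor(data[[f]])
  cells <- table(d[c(".subj", factors)])
  if (any(cells != 1)) {
    idx <- which(cells != 1, arr.ind = TRUE)[1, , drop = TRUE]
    labs <- mapply(function(dn, i) dn[i], dimnames(cells), idx)
    stop("rm_anova: design not balanced/complete at subject ", labs[1],
         ", cell (", paste(labs[-1], collapse = ", "), ")")
  }
  fixed <- paste(factors, collapse = " * ")
  form <- stats::as.formula(
    sprintf(".y ~ %s + Error(.subj/(%s))", fixed, fixed))
  fit <- stats::aov(form, data = d)
  # threshold below which a sum of squares counts as zero (guards against
  # round-off on flat data)
  ss_tot <- sum((d$.y - mean(d$.y))^2)
  eps <- 1e-12 * max(ss_tot, 1)
  out <- NULL
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    resid_row <- rn == "Residuals"
    if (!any(resid_row) || all(resid_row)) next
    ss_err <- tab[resid_row, "Sum Sq"]
    df_err <- tab[resid_row, "Df"]
    for (i in which(!resid_row)) {
      ss <- tab[i, "Sum Sq"]; df <- tab[i, "Df"]
      if (ss <= eps) {                     # flat effect: report F = 0
        f <- 0; p <- 1
      } else if (ss_err <= eps) {          # no residual variability
        f <- Inf; p <- .Machine$double.xmin
      } else {
        f <- (ss / df) / (ss_err / df_err)
        p <- stats::pf(f, df, df_err, lower.tail = FALSE)
      }
      pes <- if (ss + ss_err > 0) ss / (ss + ss_err) else 0
      out <- rbind(out, inference_result(gsub(":", " x ", rn[i]),
                                         f, df, df_err, p, pes))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("inference_result", "data.frame")
  out
}

#' @export
print.inference_result <- function(x, digits = 4, ...) {
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
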