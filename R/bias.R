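# Relative-orientation bias curves: overlapping sliding bins of the signed
# response error as a function of the angular difference between the two
# probed orientations, and the area-difference statistic that summarises
# attraction (positive) versus repulsion (negative).

#' Relative orientation of one memorised item with respect to another
#'
#' Circular difference `other - probed`, wrapped to (-pi, pi]. Negative
#' values mean the other item is clockwise of the probed item.
#'
#' @param theta_other,theta_probed Angles in radians.
#' @return Signed relative orientation(s) in (-pi, pi].
#' @examples
#' rad2deg(relative_orientation(deg2rad(10), deg2rad(30)))  # -20
#' @export
relative_orientation <- function(theta_other, theta_probed) {
  wrap_angle(theta_other - theta_probed)
}

#' Sliding-bin bias curve
#'
#' Bins paired (relative orientation, signed error) observations into
#' `n_bins` overlapping bins. Bin centres are equally spaced on the circle
#' with a half-step offset, so no centre falls on 0 or pi and the positive
#' and negative half-domains hold exactly `n_bins/2` centres each. Each bin
#' contains the `max(2, round(frac * n))` trials whose relative orientation
#' is circularly closest to the bin centre (ties broken by trial order);
#' the bin value is the arithmetic mean of those trials' signed errors.
#' Because each bin holds a fixed quarter of all trials, neighbouring bins
#' overlap heavily and the curve is strongly smoothed.
#'
#' @param deltas Relative orientations in radians.
#' @param errors Signed errors in radians, paired with `deltas`.
#' @param n_bins Number of bin centres (default 64).
#' @param frac Fraction of all trials per bin (default 1/4).
#' @return Object of class `bias_curve`: list with `centers`, `mean_bias`
#'   (both radians), `occupancy`, `n_trials`.
#' @export
sliding_bin_bias <- function(deltas, errors, n_bins = 64, frac = 1/4) {
  n <- length(deltas)
  if (length(errors) != n)
    stop("sliding_bin_bias: deltas and errors must be paired")
  if (n < 8) stop("sliding_bin_bias: need at least 8 trials")
  occupancy <- max(2L, as.integer(round(frac * n)))
  centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  deltas <- wrap_angle(deltas)
  mean_bias <- vapply(centers, function(cc) {
    d <- abs(wrap_angle(deltas - cc))
    # stable partial selection: order() is stable, so ties fall to the
    # earlier trial
    sel <- order(d)[seq_len(occupancy)]
    mean(errors[sel])
  }, numeric(1))
  structure(
    list(centers = centers, mean_bias = mean_bias,
         occupancy = occupancy, n_trials = n),
    class = "bias_curve")
}

#' Area-difference statistic of a bias curve
#'
#' Mean of the bias curve over positive relative orientations minus its mean
#' over negative relative orientations (for equally spaced centres this is
#' proportional to the difference of the two trapezoid integrals). Positive
#' values indicate attraction toward the other memorised orientation,
#' negative values repulsion away from it.
#'
#' @param curve A `bias_curve`.
#' @return Object of class `bias_stat`: list with `area_diff` (radians) and
#'   `direction` (`"attraction"`, `"repulsion"`, or `"none"`).
#' @export
area_difference <- function(curve) {
  stopifnot(inherits(curve, "bias_curve"))
  pos <- curve$centers > 0
  ad <- mean(curve$mean_bias[pos]) - mean(curve$mean_bias[!pos])
  structure(
    list(area_diff = ad,
         direction = if (ad > 0) "attraction"
                     else if (ad < 0) "repulsion" else "none"),
    class = "bias_stat")
}

#' @export
print.bias_curve <- function(x, ...) {
  cat(sprintf(
    "Bias curve: %d bins, occupancy %d of %d trials, range [%.2f, %.2f] deg\n",
    length(x$centers), x$occupancy, x$n_trials,
    rad2deg(min(x$mean_bias)), rad2deg(max(x$mean_bias))))
  invisible(x)
}

#' @export
print.bias_stat <- function(x, ...) {
  cat(sprintf("Area difference: %+.4f rad (%s)\n", x$area_diff, x$direction))
  invisible(x)
}

#' Plot a bias curve
#'
#' @param x A `bias_curve`.
#' @param degrees Plot both axes in degrees (default TRUE).
#' @param ... Passed to [plot()].
#' @export
plot.bias_curve <- function(x, degrees = TRUE, ...) {
  cx <- if (degrees) rad2deg(x$centers) else x$centers
  cy <- if (degrees) rad2deg(x$mean_bias) else x$mean_bias
  unit <- if (degrees) "deg" else "rad"
  plot(cx, cy, type = "l",
       xlab = sprintf("relative orientation (%s)", unit),
       ylab = sprintf("mean signed error (%s)", unit), ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Group test on per-subject area differences
#'
#' One-sample two-sided t test of the per-subject area-difference statistics
#' against zero, with the default JZS Bayes factor. A reliably negative mean
#' indicates group-level repulsion, a positive one attraction.
#'
#' @param area_diffs Numeric vector, one area difference per subject
#'   (length >= 3).
#' @return An `inference_result` data frame row (see [one_sample_t()]).
#' @export
bias_group_test <- function(area_diffs) {
  if (length(area_diffs) < 3)
    stop("bias_group_test: need at least 3 subjects")
  one_sample_t(area_diffs, effect = "bias_area_diff")
}
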