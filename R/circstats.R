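# Circular-angle utilities: wrapping, signed errors, resultant-based summary
# statistics, recall accuracy, and the Rayleigh uniformity test.
#
# All internal computation is in radians; degrees appear only at the file
# boundary (see read_trials/write_trials).

#' Wrap an angle to (-pi, pi]
#'
#' Reduces angles modulo 2*pi into the half-open interval (-pi, pi].
#' The lower boundary maps to the closed end, so `wrap_angle(-pi)` is `pi`.
#'
#' @param a Numeric vector of angles in radians. Must be finite.
#' @return Numeric vector of the same length, each element in (-pi, pi]
#'   and congruent to the input modulo 2*pi.
#' @examples
#' wrap_angle(deg2rad(370))  # 10 degrees
#' wrap_angle(-pi)           # pi
#' @export
wrap_angle <- function(a) {
  if (!is.numeric(a) || anyNA(a) || any(!is.finite(a)))
    stop("wrap_angle: angles must be finite numeric values")
  w <- a - 2 * pi * floor(a / (2 * pi) + 0.5)
  # floor(x + .5) rounds half up, so exactly -pi lands on -pi; fold it to +pi
  w[w <= -pi] <- pi
  w
}

#' Signed circular error of a response about a target
#'
#' Response minus target, wrapped to (-pi, pi]. Positive values are
#' counterclockwise of the target, negative values clockwise.
#'
#' @param response,target Numeric vectors of angles in radians (recycled).
#' @return Signed error(s) in (-pi, pi].
#' @examples
#' rad2deg(signed_error(deg2rad(30), deg2rad(10)))   # +20
#' rad2deg(signed_error(deg2rad(350), deg2rad(10)))  # -20
#' @export
signed_error <- function(response, target) {
  wrap_angle(response - target)
}

#' Convert degrees to radians
#' @param deg Angle(s) in degrees.
#' @return Angle(s) in radians.
#' @export
deg2rad <- function(deg) deg * pi / 180

#' Convert radians to degrees
#' @param rad Angle(s) in radians.
#' @return Angle(s) in degrees.
#' @export
rad2deg <- function(rad) rad * 180 / pi

#' Circular summary statistics
#'
#' Mean direction, mean resultant length, and circular standard deviation
#' of a sample of angles. The circular SD follows the Mardia definition
#' `sqrt(-2 * log(R))` where `R` is the mean resultant length; it is `Inf`
#' when the resultant vanishes (e.g. perfectly balanced angles).
#'
#' @param angles Numeric vector of angles in radians, length >= 2.
#' @return An object of class `circ_summary`: a list with components
#'   `mean_direction` (radians in (-pi, pi]), `resultant_length` in [0, 1],
#'   `circ_sd` (radians, possibly `Inf`), and `n`.
#' @examples
#' s <- circ_summary(c(0.1, 0.2, -0.05))
#' s$circ_sd
#' @export
circ_summary <- function(angles) {
  if (length(angles) < 2)
    stop("circ_summary: need at least 2 angles")
  if (anyNA(angles) || any(!is.finite(angles)))
    stop("circ_summary: angles must be finite")
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  R <- sqrt(C^2 + S^2)
  # guard against resultants that are zero up to round-off
  if (R < 1e-12) R <- 0
  sd <- if (R > 0) sqrt(-2 * log(R)) else Inf
  structure(
    list(mean_direction = atan2(S, C), resultant_length = R,
         circ_sd = sd, n = length(angles)),
    class = "circ_summary"
  )
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf(
    "Circular summary (n = %d): mean direction %.3f rad, R = %.3f, SD = %.3f rad\n",
    x$n, x$mean_direction, x$resultant_length, x$circ_sd))
  invisible(x)
}

#' Recall accuracy: inverse circular standard deviation
#'
#' Accuracy of continuous-report recall is the reciprocal of the circular
#' standard deviation of the signed response errors, in 1/radian. A sample
#' with zero resultant (no directional concentration at all) is assigned
#' accuracy 0 with a warning, so condition-level tables stay total.
#'
#' @param errors Signed errors in radians, length >= 2.
#' @return Nonnegative scalar accuracy (1/radian).
#' @export
recall_accuracy <- function(errors) {
  s <- circ_summary(errors)
  if (s$resultant_length == 0) {
    warning("recall_accuracy: zero resultant length; returning 0")
    return(0)
  }
  1 / s$circ_sd
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle against a unimodal alternative. The statistic is `z = n * R^2`
#' with `R` the mean resultant length. The p value uses the Wilkie (1983)
#' small-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))` (with `Rn = n * R`),
#' the same approximation used by the CircStat toolbox.
#'
#' @param angles Numeric vector of angles in radians, length >= 10.
#' @return An object of class `htest` with the statistic `z`, the p value,
#'   and the sample size.
#' @examples
#' set.seed(1)
#' rayleigh_test(rnorm(50, 0, 0.3))   # concentrated: tiny p
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 10)
    stop("rayleigh_test: need at least 10 angles")
  if (anyNA(angles) || any(!is.finite(angles)))
    stop("rayleigh_test: angles must be finite")
  Rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  Rn <- n * Rbar
  z <- n * Rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(
    list(statistic = c(z = z), p.value = p,
         parameter = c(n = n),
         method = "Rayleigh test of circular uniformity",
         data.name = deparse(substitute(angles))),
    class = "htest"
  )
}
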