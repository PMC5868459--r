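# Two-component circular mixture of a target-centred von Mises and a
# uniform guess distribution, fit to signed response errors by maximum
# likelihood:
#
#   p(e | p_mem, kappa) = p_mem * VM(e; 0, kappa) + (1 - p_mem) / (2*pi)
#
# The von Mises normalising constant is handled on the log scale
# (exponentially scaled Bessel function) so the likelihood is stable up to
# the configured kappa ceiling.

# log I0(kappa), stable for large kappa
log_bessel_i0 <- function(kappa) {
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

# von Mises log density at x (radians) with mean 0
dvonmises_log <- function(x, kappa) {
  kappa * cos(x) - log(2 * pi) - log_bessel_i0(kappa)
}

#' Log-likelihood of the von Mises + uniform mixture
#'
#' @param errors Signed errors in radians, wrapped to (-pi, pi].
#' @param p_mem Probability in [0, 1] that a response comes from the
#'   target-centred von Mises component.
#' @param kappa Nonnegative von Mises concentration.
#' @return Scalar log-likelihood.
#' @examples
#' mixture_loglik(c(0.1, -0.2, 3.0), p_mem = 0.8, kappa = 8)
#' @export
mixture_loglik <- function(errors, p_mem, kappa) {
  if (length(errors) == 0) stop("mixture_loglik: empty error vector")
  if (p_mem < 0 || p_mem > 1) stop("mixture_loglik: p_mem must be in [0, 1]")
  if (kappa < 0) stop("mixture_loglik: kappa must be nonnegative")
  # log(p_mem * vm + (1 - p_mem)/(2*pi)) via a stable two-term logsumexp
  lv <- dvonmises_log(errors, kappa)
  lu <- rep(-log(2 * pi), length(errors))
  a <- if (p_mem > 0) log(p_mem) + lv else rep(-Inf, length(errors))
  b <- if (p_mem < 1) log1p(-p_mem) + lu else rep(-Inf, length(errors))
  m <- pmax(a, b)
  sum(m + log(exp(a - m) + exp(b - m)))
}

#' Maximum-likelihood fit of the mixture model
#'
#' Maximises [mixture_loglik()] over the box `[0, 1] x [0, kappa_max]` by
#' bounded quasi-Newton (`optim` L-BFGS-B) started from every point of a
#' coarse grid; the best converged start wins. Two free parameters make
#' multi-start local optimisation both cheap and reliable here.
#'
#' @param errors Signed errors in radians.
#' @param p_starts,kappa_starts Start grids for the two parameters.
#' @param kappa_max Upper bound on kappa. The default 500 corresponds to a
#'   circular SD of about 2.6 degrees, beyond realistic motor precision.
#' @param min_n Minimum sample size (default 20).
#' @return Object of class `mixture_fit`: list with `p_mem`, `kappa`,
#'   `loglik`, `n`, `converged`, `n_starts`.
#' @examples
#' set.seed(1)
#' e <- ifelse(runif(500) < 0.7, rvonmises(500, 0, 10), runif(500, -pi, pi))
#' fit_mixture(e)
#' @export
fit_mixture <- function(errors,
                        p_starts = seq(0.1, 0.9, by = 0.2),
                        kappa_starts = c(1, 4, 16, 64),
                        kappa_max = 500,
                        min_n = 20) {
  if (length(errors) < min_n)
    stop(sprintf("fit_mixture: need at least %d errors, got %d",
                 min_n, length(errors)))
  errors <- wrap_angle(errors)
  nll <- function(par) -mixture_loglik(errors, par[1], par[2])
  starts <- expand.grid(p = p_starts, k = pmin(kappa_starts, kappa_max))
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(c(starts$p[i], starts$k[i]), nll, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(1, kappa_max)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("fit_mixture: all optimizer starts failed")
  structure(
    list(p_mem = best$par[1], kappa = best$par[2],
         loglik = -best$value, n = length(errors),
         converged = best$convergence == 0, n_starts = nrow(starts)),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Mixture fit (n = %d): P_MEM = %.3f, kappa = %.2f, logLik = %.2f%s\n",
    x$n, x$p_mem, x$kappa, x$loglik,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Exhaustive grid search over mixture parameters
#'
#' Evaluates [mixture_loglik()] at every point of a parameter lattice and
#' returns the argmax. Deterministic; ties are broken by the lowest `p_mem`
#' and then the lowest `kappa`. Serves as an exhaustive cross-check on
#' [fit_mixture()].
#'
#' @param errors Signed errors in radians.
#' @param p_values,kappa_values Lattice values for the two parameters.
#' @return List with `p_mem`, `kappa`, and `loglik` at the argmax.
#' @export
fit_mixture_grid <- function(errors, p_values, kappa_values) {
  if (length(p_values) == 0 || length(kappa_values) == 0)
    stop("fit_mixture_grid: empty grid")
  # enumerate with p varying slowest so the first maximum found has the
  # lowest p_mem, then the lowest kappa
  grid <- expand.grid(kappa = sort(kappa_values), p_mem = sort(p_values))
  ll <- vapply(seq_len(nrow(grid)),
               function(i) mixture_loglik(errors, grid$p_mem[i], grid$kappa[i]),
               numeric(1))
  best <- order(-ll, grid$p_mem, grid$kappa)[1]
  list(p_mem = grid$p_mem[best], kappa = grid$kappa[best], loglik = ll[best])
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) acceptance-rejection sampler. For `kappa` below 1e-4
#' the distribution is uniform to within double precision and is sampled
#' directly.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Nonnegative concentration.
#' @return `n` angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa) {
  if (kappa < 0) stop("rvonmises: kappa must be nonnegative")
  if (n == 0) return(numeric(0))
  if (kappa < 1e-4) return(wrap_angle(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5) * acos(pmax(pmin(f, 1), -1))
    out <- c(out, th[ok])
  }
  wrap_angle(out[seq_len(n)] + mu)
}

#' Draw signed errors from the von Mises + uniform mixture
#'
#' @param n Number of draws.
#' @param p_mem Recall probability.
#' @param kappa Concentration of the recalled component.
#' @param mu Mean of the recalled component (default 0). May be a vector of
#'   length `n` to inject a per-trial bias; guesses ignore it.
#' @param kappa Concentration; may also be a vector of length `n` (per-trial
#'   precision, used by the coupling modes of the simulator).
#' @return `n` signed errors in (-pi, pi].
#' @export
rmixture <- function(n, p_mem, kappa, mu = 0) {
  mu <- rep_len(mu, n)
  kappa <- rep_len(kappa, n)
  recalled <- stats::runif(n) < p_mem
  e <- stats::runif(n, -pi, pi)
  if (any(recalled))
    e[recalled] <- rvm_each(kappa[recalled]) + mu[recalled]
  wrap_angle(e)
}

# vectorised Best-Fisher sampler with one kappa per draw (mean 0)
rvm_each <- function(kappa) {
  n <- length(kappa)
  out <- numeric(n)
  # below ~1e-4 the von Mises is uniform to within double-precision and the
  # Best-Fisher constants suffer catastrophic cancellation
  unif <- kappa < 1e-4
  out[unif] <- stats::runif(sum(unif), -pi, pi)
  pending <- which(!unif)
  if (length(pending)) {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    while (length(pending)) {
      m <- length(pending)
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r[pending] * z) / (r[pending] + z)
      cc <- kappa[pending] * (r[pending] - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      ok[is.na(ok)] <- FALSE
      idx <- pending[ok]
      out[idx] <- sign(u3[ok] - 0.5) * acos(pmax(pmin(f[ok], 1), -1))
      pending <- pending[!ok]
    }
  }
  out
}
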