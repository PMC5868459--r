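# Shared test helpers: small designs, independent oracles.

# compact design variants so unit tests stay fast
small_e1 <- function(n_blocks = 2) design_spec("E1", n_blocks = n_blocks)

one_condition_design <- function(condition, n_trials = 160) {
  mix <- c(neutral = 0, cued_first = 0, cued_second = 0)
  mix[condition] <- n_trials
  design_spec("E1", n_blocks = 1, trials_per_block = n_trials,
              condition_mix = mix)
}

# naive per-trial mixture density summation (linear space, no log-Bessel)
naive_mixture_loglik <- function(errors, p_mem, kappa) {
  dens <- p_mem * exp(kappa * cos(errors)) / (2 * pi * besselI(kappa, 0)) +
    (1 - p_mem) / (2 * pi)
  sum(log(dens))
}

# direct sums-of-squares decomposition for a balanced fully-within design
# with one or two factors, each effect tested against its own
# effect-by-subject interaction; written with explicit mean deviations so
# it is independent of stats::aov
ss_oracle <- function(data, dv, subject, factors) {
  y <- data[[dv]]
  s <- factor(data[[subject]])
  grand <- mean(y)
  rows <- list()
  add <- function(effect, ss, df, ss_err, df_err) {
    f <- (ss / df) / (ss_err / df_err)
    rows[[length(rows) + 1]] <<- data.frame(
      effect = effect, ss = ss, df = df, ss_err = ss_err, df_err = df_err,
      f = f, p = pf(f, df, df_err, lower.tail = FALSE),
      pes = ss / (ss + ss_err))
  }
  if (length(factors) == 1) {
    a <- factor(data[[factors[1]]])
    m_a <- ave(y, a) - grand
    m_s <- ave(y, s) - grand
    resid <- y - grand - m_a - m_s
    add(factors[1], sum(m_a^2), nlevels(a) - 1,
        sum(resid^2), (nlevels(a) - 1) * (nlevels(s) - 1))
  } else if (length(factors) == 2) {
    a <- factor(data[[factors[1]]])
    b <- factor(data[[factors[2]]])
    m_a <- ave(y, a) - grand
    m_b <- ave(y, b) - grand
    m_s <- ave(y, s) - grand
    m_ab <- ave(y, a, b) - grand - m_a - m_b
    m_as <- ave(y, a, s) - grand - m_a - m_s
    m_bs <- ave(y, b, s) - grand - m_b - m_s
    m_abs <- y - grand - m_a - m_b - m_s - m_ab - m_as - m_bs
    dfa <- nlevels(a) - 1; dfb <- nlevels(b) - 1; dfs <- nlevels(s) - 1
    add(factors[1], sum(m_a^2), dfa, sum(m_as^2), dfa * dfs)
    add(factors[2], sum(m_b^2), dfb, sum(m_bs^2), dfb * dfs)
    add(paste(factors, collapse = " x "), sum(m_ab^2), dfa * dfb,
        sum(m_abs^2), dfa * dfb * dfs)
  } else stop("ss_oracle supports 1 or 2 factors")
  do.call(rbind, rows)
}
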