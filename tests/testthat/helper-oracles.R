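# Independent oracles used to cross-check the statistics layer.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (point-probability rule).
fisher_enum_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  xs <- max(0, r1 - (n - c1)):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Clopper-Pearson bounds by bisection on binomial tail probabilities.
cp_bisect <- function(x, n, alpha = 0.05) {
  tail_ge <- function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE)
  tail_le <- function(p) stats::pbinom(x, n, p)
  lo <- if (x == 0) 0 else {
    # P(X >= x | p) increases in p; solve = alpha/2
    lo <- 0; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (tail_ge(mid) > alpha / 2) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  hi <- if (x == n) 1 else {
    lo2 <- 0; hi2 <- 1
    for (i in 1:200) {
      mid <- (lo2 + hi2) / 2
      if (tail_le(mid) < alpha / 2) hi2 <- mid else lo2 <- mid
    }
    (lo2 + hi2) / 2
  }
  c(lo = lo, hi = hi)
}

# Small shared phantom fixtures (built once per test file sourcing this).
tpl128 <- aspects_template("ganglionic", shape = c(128L, 128L))
cfg128 <- function(noise_sd = 0, seed = 1L)
  phantom_config(shape = c(128L, 128L), noise_sd = noise_sd, seed = seed)
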