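# Independent oracles used to check the package's statistics. These are
# deliberately written by a different route than the implementation:
# term-by-term recurrences and literal textbook loops, never the
# special-function identities the package uses.

# Audic-Claverie pmf p(k | x) for k = 0..kmax via the term recurrence
# p(k+1)/p(k) = r (x+k+1) / ((1+r)(k+1)), r = n2/n1.
oracle_ac_pmf <- function(x, n1, n2, kmax) {
  r <- n2 / n1
  p <- numeric(kmax + 1)
  p[1] <- (1 / (1 + r))^(x + 1)
  if (kmax > 0) {
    for (k in 0:(kmax - 1)) {
      p[k + 2] <- p[k + 1] * r * (x + k + 1) / ((1 + r) * (k + 1))
    }
  }
  p
}

# Two-sided AC p-value by explicit tail summation.
oracle_ac_pvalue <- function(x, y, n1, n2) {
  pmf <- oracle_ac_pmf(x, n1, n2, max(y, 1))
  lower <- sum(pmf[1:(y + 1)])
  upper <- if (y == 0) 1 else 1 - sum(pmf[1:y])
  min(1, 2 * min(lower, upper))
}

# Literal Benjamini-Hochberg step-up, straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running_min <- 1
  for (i in m:1) {
    running_min <- min(running_min, p[ord[i]] * m / i)
    q_sorted[i] <- running_min
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Two-sided Fisher p by full hypergeometric enumeration using binomial
# coefficients directly (exact in double precision for margins <= 50).
oracle_fisher <- function(n_f, n, N_f, N) {
  k <- max(0, n + N_f - N):min(n, N_f)
  probs <- choose(N_f, k) * choose(N - N_f, n - k) / choose(N, n)
  obs <- probs[k == n_f]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}
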