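# Independent oracles shared across test files. These deliberately use
# different algorithms from the implementation paths they check.

# Coarse-grid brute-force minimizer of the NNLS objective
# ||x - a'S||^2 over the grid {0, step, ...}^3.
grid_nnls_oracle <- function(x, S, step = 0.01, upper = 1.2) {
  g <- seq(0, upper, by = step)
  G <- as.matrix(expand.grid(g, g, g))
  Q <- S %*% t(S)
  b <- as.numeric(S %*% x)
  obj <- rowSums((G %*% Q) * G) - 2 * (G %*% b)
  i <- which.min(obj)
  list(a = G[i, ], objective = obj[i] + sum(x^2))
}

# Two-sided Fisher exact p by enumerating all tables with the observed
# margins and summing hypergeometric probabilities no larger than the
# observed one.
fisher_p_oracle <- function(a, b, cc, d) {
  m <- a + b
  n <- cc + d
  k <- a + cc
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
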