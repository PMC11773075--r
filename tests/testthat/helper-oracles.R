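# Independent oracles, kept separate from the implementation paths they check.

# Brute-force maximiser of f over [lo, hi] on a fine grid.
grid_argmax <- function(f, lo, hi, n = 20001) {
  x <- seq(lo, hi, length.out = n)
  y <- vapply(x, f, numeric(1))
  i <- which.max(y)
  list(x = x[i], y = y[i], step = (hi - lo) / (n - 1))
}

# Golden-rule oracle for the discounted optimal stock: root of
#   F'(x) - c'(x) F(x) / (p - c(x)) = delta,   c(x) = c/(qx),
# solved numerically on (c/(pq), X_MEY]. Independent of the closed form.
golden_rule_stock <- function(bio, econ, delta) {
  p <- econ$price; cc <- econ$unit_cost
  K <- bio$K; q <- bio$q; r <- bio$r
  x_oa <- cc / (p * q)
  x_mey <- K / 2 + cc / (2 * p * q)
  if (delta == 0) return(x_mey)
  g <- function(x) {
    Fx <- r * x * (1 - x / K)
    r * (1 - 2 * x / K) + (cc / (q * x^2)) * Fx / (p - cc / (q * x)) - delta
  }
  lo <- if (x_oa > 0) x_oa * (1 + 1e-9) else 1e-9 * K
  stats::uniroot(g, c(lo, x_mey), tol = 1e-12 * K)$root
}

# Random feasible (bio, econ) draw with theta < 1, used by property tests.
random_fishery <- function() {
  K <- exp(runif(1, log(1e3), log(1e7)))
  q <- exp(runif(1, log(1e-7), log(1e-3)))
  r <- runif(1, 0.05, 1.5)
  p <- exp(runif(1, log(100), log(3e4)))
  theta <- runif(1, 0.02, 0.95)
  cc <- theta * p * q * K
  list(bio = biological_params(K, q, r), econ = economic_params(p, cc),
       theta = theta)
}
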