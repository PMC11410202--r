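# Shared fixtures and tiny oracles used across test files.

# Small deterministic mrdata fixture: k SNPs, n samples, exposure driven by
# the first SNP with tunable signal.
tiny_mrdata <- function(n = 40, p = 3, signal = 1, seed = 1) {
  set.seed(seed)
  g <- matrix(rbinom(n * p, 2, 0.3), n, p)
  x <- signal * g[, 1] + rnorm(n)
  y <- 0.5 * x + rnorm(n)
  mr_data(g, x, y)
}

# Brute-force OLS via explicit normal equations (independent oracle).
normal_eq_fit <- function(y, design) {
  solve(t(design) %*% design, t(design) %*% y)
}

# Moderate-signal simulated dataset shared by several tests.
demo_sim <- function(n = 600, h2 = 0.5, rho = 0.1, beta = 0.1, p_snps = 60,
                     seed = 101, ...) {
  simulate_dataset(sim_config(
    n = n, p_snps = p_snps, h2 = h2, rho = rho, beta = beta, seed = seed, ...
  ))
}

# Monte-Carlo tolerance band half-width for a proportion q at `reps`.
mc_band <- function(q, reps) 3 * sqrt(q * (1 - q) / reps)
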