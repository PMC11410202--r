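# Synthetic data generation: independent SNPs at fixed MAF, sparse causal
# effects scaled to a target exposure heritability, bivariate-normal
# confounded errors.

#' Simulation configuration
#'
#' Generative specification for one synthetic MR dataset:
#' `X = G alpha + e_x`, `Y = X beta + e_y`, with
#' `(e_x, e_y) ~ N(0, sigma2 * [[1, rho], [rho, 1]])`, independent SNPs
#' `G_j ~ Binomial(2, maf)`, and `alpha = omega0 * causal_pattern` on the
#' causal SNPs (zero elsewhere), where `omega0` is calibrated so the causal
#' SNPs explain a fraction `h2` of the exposure variance.
#'
#' @param n sample size.
#' @param p_snps total number of SNPs (default 300).
#' @param maf minor-allele frequency in (0, 0.5) (default 0.3).
#' @param causal_pattern base effect sizes of the causal SNPs; the default
#'   `c(0.4, 0.4, 0.1, 0.05, 0.05)` mixes two strong and three weaker
#'   instruments.
#' @param h2 target exposure heritability in `[0, 1)`.
#' @param rho correlation of the exposure and outcome errors (confounding).
#' @param sigma2 common error variance scale (1 by default; 5 reproduces the
#'   heavier-noise comparison setting).
#' @param beta true causal effect of the exposure on the outcome.
#' @param causal_placement `"fixed"` puts the causal SNPs in the first
#'   columns (so they can be reported as SNP 1..k); `"random"` scatters them.
#' @param seed integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n, p_snps = 300L, maf = 0.3,
                       causal_pattern = c(0.4, 0.4, 0.1, 0.05, 0.05),
                       h2 = 0.3, rho = 0.1, sigma2 = 1, beta = 0,
                       causal_placement = c("fixed", "random"), seed = 1L) {
  causal_placement <- match.arg(causal_placement)
  stopifnot(
    n >= 4L, p_snps >= 1L, maf > 0, maf < 0.5, h2 >= 0, h2 < 1,
    abs(rho) < 1, sigma2 > 0, length(causal_pattern) <= p_snps
  )
  structure(
    list(
      n = as.integer(n), p_snps = as.integer(p_snps), maf = maf,
      causal_pattern = causal_pattern, h2 = h2, rho = rho, sigma2 = sigma2,
      beta = beta, causal_placement = causal_placement,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate independent SNP dosages
#'
#' Each entry is Binomial(2, maf); columns are independent.
#'
#' @param n,p_snps,maf,seed see [sim_config()].
#' @return n x p_snps dosage matrix.
#' @export
simulate_genotypes <- function(n, p_snps, maf, seed = 1L) {
  with_seed(seed, matrix(rbinom(n * p_snps, 2L, maf), n, p_snps))
}

#' Calibrate the causal-effect scale to a target heritability
#'
#' Under independent Binomial(2, maf) SNPs, `Var(G alpha)` with
#' `alpha = omega0 * a` equals `omega0^2 * sum(a^2) * 2 maf (1 - maf)`;
#' solving `Var(G alpha) / (Var(G alpha) + sigma2_x) = h2` gives
#' `omega0 = sqrt(h2 * sigma2_x / ((1 - h2) * sum(a^2) * 2 maf (1 - maf)))`.
#'
#' @param causal_pattern base effects `a`.
#' @param maf minor-allele frequency.
#' @param h2 target heritability (`h2 = 0` returns 0; `h2 >= 1` is an error).
#' @param sigma2_x exposure error variance.
#' @return The scale `omega0`.
#' @export
calibrate_omega0 <- function(causal_pattern, maf, h2, sigma2_x = 1) {
  if (h2 >= 1) stop("h2 must be below 1")
  if (h2 < 0) stop("h2 must be nonnegative")
  if (h2 == 0) return(0)
  ssq <- sum(causal_pattern^2)
  if (ssq == 0) stop("causal pattern is identically zero")
  sqrt(h2 * sigma2_x / ((1 - h2) * ssq * 2 * maf * (1 - maf)))
}

#' Simulate one MR dataset
#'
#' Draws genotypes, calibrated causal SNP effects and bivariate-normal
#' confounded errors per the configuration, and returns the dataset together
#' with a truth record for evaluation.
#'
#' @param config a [sim_config()].
#' @return List with `data` (an [mr_data()] object) and `truth` (list with
#'   `alpha`, `beta`, `causal_idx`, `omega0`, `eps_x`, `eps_y`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 3L)
  g <- simulate_genotypes(config$n, config$p_snps, config$maf, seeds[1L])

  k <- length(config$causal_pattern)
  causal_idx <- if (config$causal_placement == "fixed") {
    seq_len(k)
  } else {
    with_seed(seeds[2L], sort(sample.int(config$p_snps, k)))
  }
  omega0 <- calibrate_omega0(
    config$causal_pattern, config$maf, config$h2, config$sigma2
  )
  alpha <- numeric(config$p_snps)
  alpha[causal_idx] <- omega0 * config$causal_pattern

  errs <- with_seed(seeds[3L], {
    e1 <- rnorm(config$n)
    e2 <- config$rho * e1 + sqrt(1 - config$rho^2) * rnorm(config$n)
    sqrt(config$sigma2) * cbind(e1, e2)
  })
  x <- as.vector(g %*% alpha) + errs[, 1L]
  y <- x * config$beta + errs[, 2L]

  list(
    data = mr_data(g, x, y, outcome_binary = FALSE),
    truth = list(
      alpha = alpha, beta = config$beta, causal_idx = causal_idx,
      omega0 = omega0, eps_x = errs[, 1L], eps_y = errs[, 2L]
    )
  )
}
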