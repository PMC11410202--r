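test_that("sis_screen ranks by absolute marginal correlation", {
  set.seed(3)
  g <- matrix(rbinom(200 * 6, 2, 0.3), 200, 6)
  x <- g[, 4] # exposure equal to one column exactly
  expect_equal(sis_screen(x, g, keep = 1), 4L)

  # keep = p returns all non-constant columns ordered by |r| descending,
  # matching a brute-force marginal-regression |t| ranking
  x2 <- 0.8 * g[, 2] - 0.5 * g[, 5] + rnorm(200)
  got <- sis_screen(x2, g, keep = 6)
  tstats <- vapply(seq_len(6), function(j) {
    abs(summary(stats::lm(x2 ~ g[, j]))$coefficients[2, 3])
  }, numeric(1))
  expect_equal(got, order(-tstats))

  # zero-variance columns are excluded with a warning
  g0 <- cbind(g, 1)
  expect_warning(got0 <- sis_screen(x2, g0, keep = 7), "zero-variance")
  expect_false(7L %in% got0)
  expect_equal(length(got0), 6L)
})

test_that("sis_screen retains all causal SNPs under strong heritability", {
  # 50 SNPs, 5 causal at h2 = 0.5: screening at keep = 25 must keep all 5,
  # and the SIS order must match the marginal-OLS |t| ranking (oracle)
  sim <- simulate_dataset(sim_config(
    n = 400, p_snps = 50, h2 = 0.5, rho = 0, beta = 0, seed = 17
  ))
  x <- sim$data$exposure
  g <- sim$data$genotypes
  kept <- sis_screen(x, g, keep = 25)
  expect_true(all(sim$truth$causal_idx %in% kept))
  tstats <- vapply(seq_len(ncol(g)), function(j) {
    abs(summary(stats::lm(x ~ g[, j]))$coefficients[2, 3])
  }, numeric(1))
  expect_equal(kept, order(-tstats)[1:25])
})

test_that("lasso_select recovers noiseless signals and stays sparse under the null", {
  set.seed(11)
  g <- matrix(rbinom(120, 2, 0.3), 60, 2)
  # single column identical to the exposure: OLS fallback, coefficient 1
  sel1 <- lasso_select(g[, 1], g[, 1, drop = FALSE])
  expect_equal(sel1$selected, 1L)
  expect_equal(sel1$alpha_hat, 1, tolerance = 1e-10)

  # pure-noise design: selections stay far below saturation across seeds
  set.seed(12)
  gn <- matrix(rbinom(150 * 40, 2, 0.3), 150, 40)
  counts <- vapply(1:20, function(s) {
    xn <- rnorm(150)
    length(lasso_select(xn, gn, seed = s)$selected)
  }, numeric(1))
  expect_lt(mean(counts), 20) # well under the 40-column saturation

  # strong-signal design: the two strongest SNPs are selected in nearly
  # every seeded replicate
  hits <- vapply(1:20, function(s) {
    sim <- simulate_dataset(sim_config(
      n = 600, p_snps = 50, h2 = 0.3, rho = 0, beta = 0, seed = 1000 + s
    ))
    sel <- lasso_select(sim$data$exposure, sim$data$genotypes, seed = s)
    all(c(1L, 2L) %in% sel$selected)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("debiased lasso approaches OLS inference in low dimension", {
  set.seed(21)
  n <- 300
  g <- matrix(rbinom(n * 8, 2, 0.3), n, 8)
  x <- 0.5 * g[, 3] + rnorm(n)
  res <- debiased_lasso_select(x, g, seed = 4)
  expect_true(3L %in% res$selected)

  ols <- summary(stats::lm(x ~ g))$coefficients[-1, ]
  # the strong coefficient's debiased estimate and p-value track OLS
  j3 <- which(res$selected == 3L)
  expect_equal(res$alpha_hat[j3], ols[3, 1], tolerance = 0.1)
  expect_lt(res$pvals[j3], 1e-6)
  # most null coefficients are not retained
  expect_lte(length(res$selected), 3L)

  # screened dimension >= sample size is a hard error
  expect_error(
    debiased_lasso_select(rnorm(6), matrix(rbinom(36, 2, 0.3), 6, 6)),
    "keep"
  )
})

test_that("lasso and debiased-lasso selectors agree on unambiguous signal", {
  sim <- simulate_dataset(sim_config(
    n = 500, p_snps = 20, causal_pattern = c(0.6, 0.6), h2 = 0.5,
    rho = 0, beta = 0, seed = 31
  ))
  x <- sim$data$exposure
  g <- sim$data$genotypes
  a <- lasso_select(x, g, seed = 1)
  b <- debiased_lasso_select(x, g, seed = 1)
  top2 <- function(sel) sel$selected[order(-abs(sel$alpha_hat))][1:2]
  expect_setequal(top2(a), c(1L, 2L))
  expect_setequal(top2(b), c(1L, 2L))
})

test_that("partial_f matches explicit normal-equations fits on a toy design", {
  # 8-observation toy with 2 selected IVs, oracle = direct linear solves
  g <- matrix(c(
    0, 1, 2, 1, 0, 2, 1, 1,
    2, 0, 1, 1, 2, 0, 1, 2
  ), 8, 2)
  x <- c(0.3, 1.1, 2.2, 0.9, 0.2, 2.5, 1.3, 0.8)
  full <- cbind(1, g)
  red <- cbind(1, g[, 1])
  rss <- function(d) sum((x - d %*% normal_eq_fit(x, d))^2)
  expected_f <- (rss(red) - rss(full)) / (rss(full) / (8 - 2 - 1))
  got <- partial_f(x, g, target = 2)
  expect_equal(got$f_value, expected_f, tolerance = 1e-10)
  expect_equal(got$rss_full, rss(full), tolerance = 1e-10)
  expect_equal(got$rss_reduced, rss(red), tolerance = 1e-10)
  expect_lte(got$rss_full, got$rss_reduced)

  # duplicated column: RSS_r = RSS_f, F = 0
  gdup <- cbind(g[, 1], g[, 1])
  expect_equal(partial_f(x, gdup, target = 2)$f_value, 0, tolerance = 1e-8)

  # single IV: partial F equals the squared t of the simple-regression slope
  t1 <- summary(stats::lm(x ~ g[, 1]))$coefficients[2, 3]
  expect_equal(partial_f(x, g[, 1, drop = FALSE], 1)$f_value, t1^2,
    tolerance = 1e-10
  )

  # too many instruments for the sample size
  expect_error(partial_f(x[1:3], g[1:3, ], 1), "n - k - 1")
})

test_that("partial F is invariant to affine rescaling of the exposure", {
  set.seed(41)
  for (rep in 1:5) {
    g <- matrix(rbinom(60 * 3, 2, 0.3), 60, 3)
    x <- g %*% c(0.4, 0, 0.2) + rnorm(60)
    f0 <- vapply(1:3, function(j) partial_f(x, g, j)$f_value, numeric(1))
    f1 <- vapply(1:3, function(j) {
      partial_f(3.7 * x - 11, g, j)$f_value
    }, numeric(1))
    expect_equal(f0, f1, tolerance = 1e-8)
  }
})

test_that("classify_ivs partitions at the threshold and is monotone", {
  sel <- list(
    selected = c(7L, 9L), alpha_hat = c(0.5, 0.4), partial_f = c(31, 29)
  )
  cls <- classify_ivs(sel, f_threshold = 30)
  expect_equal(cls$major, 7L)
  expect_equal(cls$weak, 9L)
  expect_setequal(c(cls$major, cls$weak), cls$selected)
  expect_length(intersect(cls$major, cls$weak), 0)

  # all weak when every F is under the cutoff (the common case in practice)
  cls_all_weak <- classify_ivs(
    list(selected = 1:3, alpha_hat = rep(0.1, 3), partial_f = c(2, 5, 29)),
    f_threshold = 30
  )
  expect_length(cls_all_weak$major, 0)
  expect_equal(cls_all_weak$weak, 1:3)

  # raising the threshold never adds a major IV
  set.seed(5)
  fvals <- rexp(20, rate = 0.05)
  sel20 <- list(selected = 1:20, alpha_hat = rnorm(20), partial_f = fvals)
  major50 <- classify_ivs(sel20, 50)$major
  major10 <- classify_ivs(sel20, 10)$major
  expect_true(all(major50 %in% major10))
})

test_that("select_ivs pipeline returns consistent selections", {
  sim <- demo_sim(n = 500, p_snps = 50, h2 = 0.5)
  sel <- select_ivs(sim$data$exposure, sim$data$genotypes, seed = 2)
  expect_s3_class(sel, "iv_selection")
  expect_equal(length(sel$selected), length(sel$alpha_hat))
  expect_equal(length(sel$selected), length(sel$partial_f))
  expect_setequal(c(sel$major, sel$weak), sel$selected)
  expect_true(all(sel$partial_f[match(sel$major, sel$selected)] > 30))
  expect_true(all(sel$partial_f[match(sel$weak, sel$selected)] <= 30))

  # post-selection OLS refit changes estimates but not the selected set
  sel_refit <- select_ivs(sim$data$exposure, sim$data$genotypes,
    seed = 2, refit_alpha = TRUE
  )
  expect_equal(sel_refit$selected, sel$selected)
  expect_false(isTRUE(all.equal(sel_refit$alpha_hat, sel$alpha_hat)))

  # empty result (constant SNPs) is an empty selection, not an error
  g_const <- matrix(1, 50, 3)
  suppressWarnings(
    sel0 <- select_ivs(rnorm(50), g_const, seed = 1)
  )
  expect_length(sel0$selected, 0)
})
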