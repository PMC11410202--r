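test_that("make_split partitions into near-equal halves, reproducibly", {
  p10 <- make_split(10, seed = 3)
  expect_length(p10$i1, 5)
  expect_length(p10$i2, 5)
  expect_setequal(c(p10$i1, p10$i2), 1:10)
  expect_length(intersect(p10$i1, p10$i2), 0)

  p11 <- make_split(11, seed = 3)
  expect_length(p11$i1, 5) # floor(n/2)
  expect_length(p11$i2, 6)

  expect_identical(make_split(10, seed = 7), make_split(10, seed = 7))
  expect_error(make_split(3, seed = 1), "at least 4")
})

test_that("composite weights are L1-normalized and sign-preserving", {
  expect_equal(composite_weights(0.5), 1)
  expect_equal(composite_weights(c(0.2, -0.2)), c(0.5, -0.5))
  expect_equal(composite_weights(c(0.3, -0.1, 0.2)), c(0.5, -1 / 6, 1 / 3))
  expect_error(composite_weights(numeric(0)), "no weak")
  expect_error(composite_weights(c(0, 0)), "zero")

  set.seed(8)
  for (rep in 1:5) {
    a <- rnorm(sample(1:10, 1))
    w <- composite_weights(a)
    expect_equal(sum(abs(w)), 1, tolerance = 1e-12)
    expect_equal(sign(w), sign(a))
  }
})

test_that("build_composite forms the weighted dosage sum", {
  g <- matrix(c(
    0, 1, 2, 1, 0, 2,
    2, 2, 0, 1, 1, 0,
    1, 0, 1, 2, 0, 1
  ), 6, 3)

  # single weak IV with weight 1: composite equals that dosage column
  one <- build_composite(g, weak_indices = 2L, weights = 1)
  expect_equal(one$values, g[, 2])

  # two identical columns, weights (0.5, 0.5): composite equals the column
  gid <- cbind(g[, 1], g[, 1])
  expect_equal(
    build_composite(gid, 1:2, c(0.5, 0.5))$values, g[, 1]
  )

  # hand-computed weighted sums on printed dosages
  got <- build_composite(g, c(1L, 3L), c(0.5, -0.5))
  expect_equal(got$values, 0.5 * g[, 1] - 0.5 * g[, 3])
  expect_equal(
    got$values,
    c(-0.5, 0.5, 0.5, -0.5, 0, 0.5)
  )

  expect_error(build_composite(g, 4L, 1), "out of range")
  expect_error(build_composite(g, 1:2, 1), "equal length")
})

test_that("fit_first_stage reproduces OLS fitted values", {
  # perfect instrument: composite proportional to the exposure
  x <- c(0.5, 1.5, 2.5, 0.1, 1.1, 2.1, 0.7, 1.7)
  comp <- structure(list(values = 2 * x + 3), class = "composite_iv")
  expect_equal(fit_first_stage(x, NULL, comp), x, tolerance = 1e-10)

  # oracle: explicit normal-equations solve on an 8-sample toy
  set.seed(9)
  majors <- matrix(rbinom(16, 2, 0.4), 8, 2)
  comp2 <- structure(list(values = rnorm(8)), class = "composite_iv")
  x2 <- rnorm(8)
  design <- cbind(1, majors, comp2$values)
  expected <- as.vector(design %*% normal_eq_fit(x2, design))
  expect_equal(fit_first_stage(x2, majors, comp2), expected,
    tolerance = 1e-10
  )

  expect_error(fit_first_stage(x2, NULL, NULL), "no first-stage regressors")
  # collinear design: warned, fitted values still returned
  expect_warning(
    f <- fit_first_stage(x2, cbind(majors, majors[, 1]), NULL),
    "rank-deficient"
  )
  expect_length(f, 8)
})

test_that("run_single_split cross-fits: weights depend only on the opposite half", {
  sim <- demo_sim(n = 400, p_snps = 40)
  plan <- make_split(400, seed = 12)
  sr <- run_single_split(sim$data, plan = plan, seed = 12)
  expect_s3_class(sr, "split_result")
  expect_equal(sr$status, "ok")

  # perturb the exposure only inside half 1; the selection used for half 1
  # (trained on half 2) must be unchanged
  pert <- sim$data
  pert$exposure[plan$i1] <- pert$exposure[plan$i1] + rnorm(length(plan$i1))
  pert <- mr_data(pert$genotypes, pert$exposure, pert$outcome)
  sr_pert <- run_single_split(pert, plan = plan, seed = 12)
  expect_equal(
    sr_pert$selections[[1]]$selected, sr$selections[[1]]$selected
  )
  expect_equal(
    sr_pert$selections[[1]]$alpha_hat, sr$selections[[1]]$alpha_hat,
    tolerance = 1e-12
  )
})

test_that("cross-fitted exposures are stacked in original sample order", {
  sim <- demo_sim(n = 300, p_snps = 30)
  plan <- make_split(300, seed = 4)
  sr <- run_single_split(sim$data, plan = plan, seed = 4, keep_fitted = TRUE)
  expect_equal(sr$status, "ok")
  xhat <- sr$fitted_exposure
  expect_length(xhat, 300)
  expect_false(anyNA(xhat))

  # recompute half 1's first stage by hand from the selection trained on I2
  sel <- sr$selections[[1]]
  g1 <- sim$data$genotypes[plan$i1, , drop = FALSE]
  comp <- if (length(sel$weak) > 0) {
    build_composite(g1, sel$weak, composite_weights(sel$alpha_weak))
  } else {
    NULL
  }
  manual <- fit_first_stage(
    sim$data$exposure[plan$i1], g1[, sel$major, drop = FALSE], comp
  )
  expect_equal(xhat[plan$i1], manual, tolerance = 1e-10)
})

test_that("estimates are invariant to joint permutation of rows, plan and selections", {
  sim <- demo_sim(n = 300, p_snps = 30)
  plan <- make_split(300, seed = 6)
  sr <- run_single_split(sim$data, plan = plan, seed = 6)
  expect_equal(sr$status, "ok")

  perm <- withr::with_seed(99, sample(300))
  data_p <- mr_data(
    sim$data$genotypes[perm, , drop = FALSE],
    sim$data$exposure[perm], sim$data$outcome[perm]
  )
  inv <- order(perm) # position of original sample i in the permuted data
  plan_p <- structure(
    list(seed = plan$seed, i1 = sort(inv[plan$i1]), i2 = sort(inv[plan$i2])),
    class = "split_plan"
  )
  sr_p <- run_single_split(
    data_p,
    plan = plan_p, selections = sr$selections
  )
  expect_equal(sr_p$beta, sr$beta, tolerance = 1e-10)
  expect_equal(sr_p$se, sr$se, tolerance = 1e-10)
  expect_equal(sr_p$pval, sr$pval, tolerance = 1e-10)
})

test_that("degenerate data fails the split instead of raising", {
  # constant SNPs: screening is empty, so selection is empty in both halves
  g <- matrix(1, 60, 4)
  d <- mr_data(g, rnorm(60), rnorm(60))
  suppressWarnings(sr <- run_single_split(d, seed = 2))
  expect_equal(sr$status, "failed")
  expect_match(sr$note, "empty IV selection")
  expect_true(is.na(sr$beta))
})
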