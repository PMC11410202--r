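# Shared, lazily computed Monte-Carlo studies for the acceptance tests.
# Several criteria read different summaries of the same simulation cell, so
# each study is computed once per test run and cached.
#
# Study sizes are desk-scale: replicate counts are chosen so each study runs
# in minutes on one CPU, and every probabilistic check uses the matching
# Monte-Carlo tolerance band (3 standard errors at the realized replicate
# count) rather than the tolerances a 1000-replicate study would support.

.acc_cache <- new.env(parent = emptyenv())

acc_cached <- function(key, expr) {
  if (!exists(key, envir = .acc_cache)) {
    assign(key, force(expr), envir = .acc_cache)
  }
  get(key, envir = .acc_cache)
}

ACC_REPS_CELL <- 150L # estimator-comparison cells
ACC_REPS_T1 <- 80L # type-I grid cells
ACC_REPS_ID <- 100L # identification study
ACC_REPS_THM <- 100L # variance-dominance study
ACC_REPS_SPLIT <- 15L # split-count stability study

# One Table-2-style cell: single-split MR-SPLIT vs half-sample 2SLS/LIML.
acc_cell <- function(h2, rho, beta, methods = c("mrsplit", "2sls", "liml"),
                     reps = ACC_REPS_CELL, seed = 20240906) {
  key <- paste("cell", h2, rho, beta, paste(methods, collapse = ""), sep = "_")
  acc_cached(key, {
    run_estimator_study(
      sim_config(n = 1000, h2 = h2, rho = rho, beta = beta),
      methods = methods, reps = reps, master_seed = seed
    )
  })
}

acc_row <- function(tab, method) tab[tab$method == method, , drop = FALSE]

# 3-MC-SE band for the mean-bias scale (x100), from the realized spread.
bias_band <- function(row) 3 * 100 * row$emp_sd / sqrt(row$reps)

acc_type1_grid <- function() {
  acc_cached("type1", {
    grid <- expand.grid(h2 = c(0.15, 0.3, 0.5), rho = c(0.1, 0.2))
    configs <- lapply(seq_len(nrow(grid)), function(i) {
      sim_config(n = 1000, h2 = grid$h2[i], rho = grid$rho[i], beta = 0)
    })
    run_estimator_study(
      configs,
      methods = c("mrsplit", "2sls"), reps = ACC_REPS_T1,
      master_seed = 1133
    )
  })
}

acc_identification <- function() {
  acc_cached("ident", {
    rbind(
      run_major_iv_study(
        h2_values = 0.5, n_values = 2000, f_thresholds = c(10, 30, 50),
        reps = ACC_REPS_ID, master_seed = 515
      ),
      run_major_iv_study(
        h2_values = 0.15, n_values = 500, f_thresholds = c(10, 30, 50),
        reps = ACC_REPS_ID, master_seed = 516
      )
    )
  })
}

# Variance-dominance study: single-split MR-SPLIT vs 2-fold CFMR on the
# heavier-noise comparison setting (sigma2 = 5, rho = 0.16).
acc_theorem1 <- function() {
  acc_cached("thm1", {
    configs <- lapply(c(0.15, 0.3), function(h2) {
      sim_config(n = 1000, h2 = h2, rho = 0.16, sigma2 = 5, beta = 0.08)
    })
    run_estimator_study(
      configs,
      methods = c("mrsplit", "cfmr"), reps = ACC_REPS_THM,
      master_seed = 616, cfmr_folds = 2L
    )
  })
}

acc_split_counts <- function() {
  acc_cached("splitcount", {
    run_split_count_study(
      n_values = 500, betas = 0.2, split_counts = c(10, 30, 50, 80),
      reps = ACC_REPS_SPLIT, master_seed = 717, h2 = 0.15
    )
  })
}
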