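# Monte-Carlo studies: estimator comparison (bias / SE / coverage /
# rejection), major-IV identification, and split-count stability.

#' @noRd
subset_mrdata <- function(data, idx) {
  mr_data(
    data$genotypes[idx, , drop = FALSE], data$exposure[idx],
    data$outcome[idx],
    sample_ids = data$sample_ids[idx],
    snp_ids = data$snp_ids, outcome_binary = data$outcome_binary
  )
}

#' Compare estimators over a grid of simulation settings
#'
#' For each configuration and replicate, a dataset is generated and analysed
#' by the requested estimators.  With `split_mode = "half"` (the default),
#' the sample is split once: instruments are selected on one half and plain
#' 2SLS/LIML estimate on the other half with all selected instruments, while
#' MR-SPLIT runs its usual single 2-fold split (selection on each complement,
#' cross-fitted composite instruments, full-sample second stage) sharing the
#' same split and the same half-sample selections.  With
#' `split_mode = "none"`, 2SLS/LIML select and estimate on the whole sample —
#' the winner's-curse demonstration.  CFMR uses its own `cfmr_folds`-fold
#' cross-fitting.
#'
#' @param configs a [sim_config()] or list of them (the per-config `seed` is
#'   ignored; replicate seeds derive from `master_seed`).
#' @param methods subset of `c("mrsplit", "2sls", "liml", "cfmr")`.
#' @param reps replicates per configuration.
#' @param master_seed integer seed for the whole study.
#' @param f_threshold,selector,keep passed to the selection machinery.
#' @param split_mode `"half"` or `"none"` (affects 2SLS/LIML only).
#' @param cfmr_folds fold count for CFMR.
#' @param level nominal two-sided test level / CI coverage target.
#' @param verbose log one line per configuration.
#' @return Data frame with one row per configuration x method: `bias_x100`
#'   (`|beta - mean(beta_hat)| * 100`), `est_se` (mean estimated SE),
#'   `emp_sd` (empirical SD of estimates), `coverage`, `rejection`, `reps`,
#'   `n_fail`.  Per-replicate draws are attached as attribute `draws`.
#' @export
run_estimator_study <- function(configs, methods = c("mrsplit", "2sls", "liml"),
                                reps = 200L, master_seed = 1L,
                                f_threshold = 30, selector = "lasso",
                                keep = NULL, split_mode = c("half", "none"),
                                cfmr_folds = 10L, level = 0.05,
                                verbose = FALSE) {
  split_mode <- match.arg(split_mode)
  if (inherits(configs, "sim_config")) configs <- list(configs)
  methods <- match.arg(methods,
    c("mrsplit", "2sls", "liml", "cfmr"),
    several.ok = TRUE
  )
  cell_seeds <- matrix(
    derive_seeds(master_seed, length(configs) * reps),
    nrow = reps
  )

  rows <- list()
  draws <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    res <- replicate_cell(
      cfg, methods, reps, cell_seeds[, ci], f_threshold, selector, keep,
      split_mode, cfmr_folds
    )
    for (m in methods) {
      d <- res[[m]]
      ok <- is.finite(d$beta)
      crit_z <- qnorm(1 - level / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        n = cfg$n, h2 = cfg$h2, rho = cfg$rho, beta = cfg$beta,
        sigma2 = cfg$sigma2, method = m,
        bias_x100 = abs(cfg$beta - mean(d$beta[ok])) * 100,
        est_se = mean(d$se[ok]),
        emp_sd = sd(d$beta[ok]),
        coverage = mean(d$cover[ok]),
        rejection = mean(d$pval[ok] < level),
        reps = sum(ok), n_fail = sum(!ok)
      )
      draws[[paste(ci, m, sep = ".")]] <- d
    }
    msg(
      "config %d/%d done (n=%d h2=%.2f rho=%.2f beta=%.2f)",
      ci, length(configs), cfg$n, cfg$h2, cfg$rho, cfg$beta,
      verbose = verbose
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "draws") <- draws
  out
}

#' @noRd
replicate_cell <- function(cfg, methods, reps, rep_seeds, f_threshold,
                           selector, keep, split_mode, cfmr_folds) {
  empty <- function() {
    data.frame(
      beta = rep(NA_real_, reps), se = NA_real_, pval = NA_real_,
      cover = NA
    )
  }
  res <- stats::setNames(
    lapply(methods, function(m) empty()), methods
  )
  for (r in seq_len(reps)) {
    s <- derive_seeds(rep_seeds[r], 5L)
    cfg_r <- cfg
    cfg_r$seed <- s[1L]
    sim <- simulate_dataset(cfg_r)
    data <- sim$data
    n <- cfg$n
    plan <- make_split(n, s[2L])

    need_half_sel <- split_mode == "half" &&
      any(c("mrsplit", "2sls", "liml") %in% methods)
    sel_i1 <- NULL
    if (need_half_sel) {
      sel_i1 <- select_ivs(
        data$exposure[plan$i1], data$genotypes[plan$i1, , drop = FALSE],
        keep = keep, selector = selector, f_threshold = f_threshold,
        seed = s[3L], half_id = 1L
      )
    }

    record <- function(m, est, beta_true) {
      res[[m]]$beta[r] <<- est$beta_hat
      res[[m]]$se[r] <<- est$se
      res[[m]]$pval[r] <<- est$pval
      res[[m]]$cover[r] <<- est$ci_low <= beta_true & beta_true <= est$ci_high
    }

    if ("mrsplit" %in% methods) {
      sel_i2 <- select_ivs(
        data$exposure[plan$i2], data$genotypes[plan$i2, , drop = FALSE],
        keep = keep, selector = selector, f_threshold = f_threshold,
        seed = s[4L], half_id = 2L
      )
      # selections[[k]] must be trained on the complement of half k
      sr <- run_single_split(
        data,
        plan = plan, f_threshold = f_threshold,
        selections = list(sel_i2, sel_i1)
      )
      if (sr$status == "ok") {
        record("mrsplit", list(
          beta_hat = sr$beta, se = sr$se, pval = sr$pval,
          ci_low = sr$ci[1L], ci_high = sr$ci[2L]
        ), cfg$beta)
      }
    }

    for (m in intersect(c("2sls", "liml"), methods)) {
      est <- tryCatch(
        {
          if (split_mode == "half") {
            if (length(sel_i1$selected) == 0L) stop("empty selection")
            sub <- subset_mrdata(data, plan$i2)
            if (m == "2sls") {
              tsls_full(sub, sel_i1$selected)
            } else {
              liml(sub, sel_i1$selected)
            }
          } else {
            sel_full <- select_ivs(
              data$exposure, data$genotypes,
              keep = keep,
              selector = selector, f_threshold = f_threshold, seed = s[3L]
            )
            if (length(sel_full$selected) == 0L) stop("empty selection")
            if (m == "2sls") {
              tsls_full(data, sel_full$selected)
            } else {
              liml(data, sel_full$selected)
            }
          }
        },
        error = function(e) NULL
      )
      if (!is.null(est)) record(m, est, cfg$beta)
    }

    if ("cfmr" %in% methods) {
      est <- tryCatch(
        cfmr(data, k_folds = cfmr_folds, keep = keep, seed = s[5L]),
        error = function(e) NULL
      )
      if (!is.null(est)) record("cfmr", est, cfg$beta)
    }
  }
  res
}

#' Major-instrument identification study
#'
#' For each (heritability, sample size) cell, repeatedly simulates a dataset,
#' selects instruments on the whole sample (SIS + LASSO), computes each
#' selected instrument's partial F, and classifies major instruments at each
#' threshold.  Reports, per causal SNP, the fraction of replicates in which
#' it is classified major, and the mean count of non-causal (noise) SNPs
#' classified major.
#'
#' @param h2_values,n_values grid of heritabilities and sample sizes.
#' @param f_thresholds partial-F cutoffs to evaluate.
#' @param reps replicates per cell.
#' @param master_seed integer seed.
#' @param p_snps,maf,causal_pattern,sigma2 generative settings.
#' @param keep,selector selection settings (default SIS keep: half of `n`).
#' @return Data frame with columns `h2`, `n`, `f_threshold`, one `snpJ`
#'   column per causal SNP, and `noise`.
#' @export
run_major_iv_study <- function(h2_values, n_values, f_thresholds = c(10, 30, 50),
                               reps = 200L, master_seed = 1L, p_snps = 300L,
                               maf = 0.3,
                               causal_pattern = c(0.4, 0.4, 0.1, 0.05, 0.05),
                               sigma2 = 1, keep = NULL, selector = "lasso") {
  k <- length(causal_pattern)
  grid <- expand.grid(h2 = h2_values, n = n_values)
  cell_seeds <- matrix(derive_seeds(master_seed, nrow(grid) * reps),
    nrow = reps
  )

  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    h2 <- grid$h2[ci]
    n <- grid$n[ci]
    major_counts <- matrix(0, length(f_thresholds), k)
    noise_counts <- numeric(length(f_thresholds))
    for (r in seq_len(reps)) {
      s <- derive_seeds(cell_seeds[r, ci], 2L)
      cfg <- sim_config(
        n = n, p_snps = p_snps, maf = maf, causal_pattern = causal_pattern,
        h2 = h2, rho = 0, sigma2 = sigma2, beta = 0,
        causal_placement = "fixed", seed = s[1L]
      )
      sim <- simulate_dataset(cfg)
      sel <- select_ivs(
        sim$data$exposure, sim$data$genotypes,
        keep = keep,
        selector = selector, seed = s[2L]
      )
      for (ti in seq_along(f_thresholds)) {
        major <- sel$selected[sel$partial_f > f_thresholds[ti]]
        major_counts[ti, ] <- major_counts[ti, ] +
          as.numeric(seq_len(k) %in% major)
        noise_counts[ti] <- noise_counts[ti] + sum(major > k)
      }
    }
    for (ti in seq_along(f_thresholds)) {
      row <- data.frame(h2 = h2, n = n, f_threshold = f_thresholds[ti])
      snp_means <- major_counts[ti, ] / reps
      names(snp_means) <- paste0("snp", seq_len(k))
      row <- cbind(row, as.data.frame(as.list(snp_means)))
      row$noise <- noise_counts[ti] / reps
      row$reps <- reps
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Split-count stability study
#'
#' Evaluates how the MR-SPLIT rejection rate at the nominal level changes
#' with the number of random splits `L`.  Each replicate runs
#' `max(split_counts)` splits once; the Cauchy-combined p-value for every
#' smaller `L` is computed from the first `L` splits, so the curve across
#' `L` is internally consistent.
#'
#' @param n_values sample sizes.
#' @param betas true causal effects (use 0 for type-I error, nonzero for
#'   power).
#' @param split_counts ascending split counts to evaluate.
#' @param reps replicates per cell.
#' @param master_seed integer seed.
#' @param h2,rho,sigma2,p_snps,maf,causal_pattern generative settings.
#' @param f_threshold,selector,keep selection settings.
#' @param level rejection threshold.
#' @return Data frame with columns `n`, `h2`, `beta`, `splits`, `rejection`,
#'   `reps`.
#' @export
run_split_count_study <- function(n_values, betas = c(0, 0.2),
                                  split_counts = c(10, 30, 50, 80),
                                  reps = 100L, master_seed = 1L, h2 = 0.15,
                                  rho = 0.16, sigma2 = 5, p_snps = 300L,
                                  maf = 0.3,
                                  causal_pattern = c(0.4, 0.4, 0.1, 0.05, 0.05),
                                  f_threshold = 30, selector = "lasso",
                                  keep = NULL, level = 0.05) {
  stopifnot(!is.unsorted(split_counts))
  l_max <- max(split_counts)
  grid <- expand.grid(n = n_values, beta = betas)
  cell_seeds <- matrix(derive_seeds(master_seed, nrow(grid) * reps),
    nrow = reps
  )

  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    n <- grid$n[ci]
    beta <- grid$beta[ci]
    reject <- matrix(NA, reps, length(split_counts))
    for (r in seq_len(reps)) {
      s <- derive_seeds(cell_seeds[r, ci], 2L)
      cfg <- sim_config(
        n = n, p_snps = p_snps, maf = maf, causal_pattern = causal_pattern,
        h2 = h2, rho = rho, sigma2 = sigma2, beta = beta, seed = s[1L]
      )
      sim <- simulate_dataset(cfg)
      fit <- tryCatch(
        mr_split(sim$data,
          n_splits = l_max, f_threshold = f_threshold,
          selector = selector, keep = keep, master_seed = s[2L],
          min_success = 1L
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      pvals <- vapply(fit$splits, `[[`, numeric(1), "pval")
      for (li in seq_along(split_counts)) {
        p_l <- pvals[seq_len(split_counts[li])]
        p_l <- p_l[is.finite(p_l)]
        if (length(p_l) == 0L) next
        reject[r, li] <- cauchy_combine(p_l)$p_combined < level
      }
    }
    for (li in seq_along(split_counts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, h2 = h2, beta = beta, splits = split_counts[li],
        rejection = mean(reject[, li], na.rm = TRUE),
        reps = sum(is.finite(reject[, li]))
      )
    }
  }
  do.call(rbind, rows)
}
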