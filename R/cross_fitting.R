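# One random 2-fold split end-to-end: opposite-half IV selection, composite
# instrument construction, cross-fitted exposures, split-level estimate.

#' Draw a random 2-fold split plan
#'
#' Partitions `1:n` uniformly at random into `i1` (size `floor(n/2)`) and its
#' complement `i2`, reproducibly from `seed`.
#'
#' @param n sample count (>= 4).
#' @param seed integer seed.
#' @return Object of class `split_plan` with `seed`, `i1`, `i2`.
#' @export
make_split <- function(n, seed) {
  if (n < 4L) stop("need at least 4 samples to split")
  i1 <- with_seed(seed, sort(sample.int(n, floor(n / 2))))
  structure(
    list(seed = as.integer(seed), i1 = i1, i2 = setdiff(seq_len(n), i1)),
    class = "split_plan"
  )
}

#' Composite-instrument weights from weak-IV effect estimates
#'
#' `w_j = alpha_j / sum(|alpha_j|)`: sign-preserving and L1-normalized, so
#' `sum(|w_j|) = 1` and `sign(w_j) = sign(alpha_j)`.
#'
#' @param alpha_hat_weak signed effect estimates of the weak instruments,
#'   estimated on the opposite half-sample.
#' @return Numeric weight vector.
#' @export
composite_weights <- function(alpha_hat_weak) {
  if (length(alpha_hat_weak) == 0L) stop("no weak instruments to weight")
  total <- sum(abs(alpha_hat_weak))
  if (total == 0) stop("all weak-IV effect estimates are zero; cannot weight")
  alpha_hat_weak / total
}

#' Build the composite instrument on the target half
#'
#' Weighted sum of the target half's dosage columns for the weak instruments,
#' with weights trained on the opposite half (the cross-fitting contract).
#'
#' @param genotypes_target_half dosage matrix of the target half.
#' @param weak_indices weak-instrument column indices.
#' @param weights output of [composite_weights()], aligned with
#'   `weak_indices`.
#' @return Object of class `composite_iv` with `values`, `weights`,
#'   `weak_indices`.
#' @export
build_composite <- function(genotypes_target_half, weak_indices, weights) {
  g <- as.matrix(genotypes_target_half)
  if (length(weak_indices) != length(weights)) {
    stop("weak_indices and weights must have equal length")
  }
  if (any(weak_indices < 1L) || any(weak_indices > ncol(g))) {
    stop("weak instrument index out of range for the target half")
  }
  structure(
    list(
      values = as.vector(g[, weak_indices, drop = FALSE] %*% weights),
      weights = weights, weak_indices = weak_indices
    ),
    class = "composite_iv"
  )
}

#' First-stage regression within one half
#'
#' OLS fitted values of the exposure on an intercept, the major-instrument
#' dosage columns, and the composite instrument (either component may be
#' absent, but not both).  Collinear columns are dropped with a warning.
#'
#' @param exposure_half exposure values of the half.
#' @param major_columns dosage matrix of major instruments (may have zero
#'   columns or be `NULL`).
#' @param composite a [build_composite()] object, or `NULL`.
#' @return Numeric vector of fitted exposures.
#' @export
fit_first_stage <- function(exposure_half, major_columns = NULL,
                            composite = NULL) {
  n <- length(exposure_half)
  design <- matrix(1, n, 1L)
  if (!is.null(major_columns) && ncol(as.matrix(major_columns)) > 0L) {
    design <- cbind(design, as.matrix(major_columns))
  }
  if (!is.null(composite)) design <- cbind(design, composite$values)
  if (ncol(design) == 1L) {
    stop("no first-stage regressors: need at least one major or composite IV")
  }
  fit <- lm.fit(design, exposure_half)
  if (fit$rank < ncol(design)) {
    warning(sprintf(
      "first-stage design rank-deficient (%d of %d); collinear columns dropped",
      fit$rank, ncol(design)
    ))
  }
  as.vector(exposure_half - fit$residuals)
}

#' Run one 2-fold split of the MR-SPLIT pipeline
#'
#' For each half `I_k`, instruments are selected and their effects estimated
#' on the complement, classified into major and weak by partial F, the weak
#' ones consolidated into a composite instrument on `I_k`, and the first
#' stage fitted on `I_k`.  The cross-fitted exposures are stacked in the
#' original sample order and the causal effect estimated by
#' [tsls_second_stage()].  An empty selection in either half marks the split
#' `failed` (no exception): there is then no instrument for that half.
#'
#' @param data an [mr_data()] object.
#' @param plan a [make_split()] plan (defaults to a fresh plan under `seed`).
#' @param f_threshold major-instrument partial-F cutoff.
#' @param selector,keep,p_threshold,refit_alpha passed to [select_ivs()].
#' @param seed integer seed (used for the plan when `plan` is `NULL`, and
#'   for CV fold assignments).
#' @param selections optional list of two precomputed `iv_selection` objects,
#'   element `k` trained on the complement of half `k` (used by the study
#'   harness to share selections across estimators).
#' @param keep_fitted if `TRUE`, retain the stacked fitted exposure vector.
#' @param verbose emit a per-split log line.
#' @return Object of class `split_result`.
#' @export
run_single_split <- function(data, plan = NULL, f_threshold = 30,
                             selector = c("lasso", "dlasso"), keep = NULL,
                             p_threshold = 0.05, refit_alpha = FALSE,
                             seed = 1L, selections = NULL,
                             keep_fitted = FALSE, verbose = FALSE) {
  stopifnot(inherits(data, "mrdata"))
  selector <- match.arg(selector)
  n <- length(data$exposure)
  if (is.null(plan)) plan <- make_split(n, seed)
  halves <- list(plan$i1, plan$i2)
  half_seeds <- derive_seeds(plan$seed, 2L)

  failed <- function(note) {
    structure(
      list(
        status = "failed", note = note, beta = NA_real_, se = NA_real_,
        pval = NA_real_, ci = c(NA_real_, NA_real_),
        n_selected = NA_real_, n_major = NA_real_, n_weak = NA_real_,
        plan = plan, fitted_exposure = NULL, selections = NULL
      ),
      class = "split_result"
    )
  }

  xhat <- rep(NA_real_, n)
  sels <- vector("list", 2L)
  for (k in 1:2) {
    target <- halves[[k]]
    train <- halves[[if (k == 1L) 2L else 1L]] # complement of I_k
    sel <- if (!is.null(selections)) {
      selections[[k]]
    } else {
      select_ivs(
        data$exposure[train], data$genotypes[train, , drop = FALSE],
        keep = keep, selector = selector, f_threshold = f_threshold,
        p_threshold = p_threshold, refit_alpha = refit_alpha,
        seed = half_seeds[k], half_id = if (k == 1L) 2L else 1L
      )
    }
    sels[[k]] <- sel
    if (length(sel$selected) == 0L) {
      return(failed(sprintf("empty IV selection for half %d", k)))
    }

    composite <- NULL
    if (length(sel$weak) > 0L && sum(abs(sel$alpha_weak)) > 0) {
      w <- composite_weights(sel$alpha_weak)
      composite <- build_composite(
        data$genotypes[target, , drop = FALSE], sel$weak, w
      )
    }
    majors <- data$genotypes[target, sel$major, drop = FALSE]
    if (is.null(composite) && ncol(majors) == 0L) {
      return(failed(sprintf("no usable instrument for half %d", k)))
    }
    xhat[target] <- fit_first_stage(data$exposure[target], majors, composite)
  }

  if (sd(xhat) == 0) return(failed("constant cross-fitted exposure"))
  est <- tsls_second_stage(
    data$outcome, xhat, data$exposure, data$outcome_binary
  )
  n_major <- mean(vapply(sels, function(s) length(s$major), numeric(1)))
  n_weak <- mean(vapply(sels, function(s) length(s$weak), numeric(1)))
  n_selected <- mean(vapply(sels, function(s) length(s$selected), numeric(1)))
  msg(
    "split seed=%d: selected=%.1f major=%.1f weak=%.1f beta=%.4f p=%.3g",
    plan$seed, n_selected, n_major, n_weak, est$beta_hat, est$pval,
    verbose = verbose
  )
  structure(
    list(
      status = "ok", note = "", beta = est$beta_hat, se = est$se,
      pval = est$pval, ci = c(est$ci_low, est$ci_high),
      n_selected = n_selected, n_major = n_major, n_weak = n_weak,
      plan = plan,
      fitted_exposure = if (keep_fitted) xhat else NULL,
      selections = sels
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  if (x$status == "failed") {
    cat(sprintf("<split_result> failed: %s\n", x$note))
  } else {
    cat(sprintf(
      "<split_result> beta=%.4f se=%.4f p=%.3g (major=%.1f weak=%.1f per half)\n",
      x$beta, x$se, x$pval, x$n_major, x$n_weak
    ))
  }
  invisible(x)
}
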