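# Instrument selection within a half-sample: SIS screening, (debiased) LASSO
# selection, partial F-statistics, and major/weak classification.

#' Sure independence screening
#'
#' Ranks SNP columns by absolute marginal correlation with the exposure
#' (equivalent to ranking marginal-regression |t| statistics) and keeps the
#' top `keep`.  Zero-variance columns are excluded from the ranking with a
#' warning.  Ties are broken by ascending column index, so the result is
#' deterministic.
#'
#' @param exposure numeric vector.
#' @param genotypes matrix with rows aligned to `exposure`.
#' @param keep number of columns to retain (capped at the number of
#'   non-constant columns).
#' @return Integer vector of column indices, ordered by decreasing |r|.
#' @export
sis_screen <- function(exposure, genotypes, keep) {
  genotypes <- as.matrix(genotypes)
  stopifnot(length(exposure) == nrow(genotypes), keep >= 1)
  sds <- apply(genotypes, 2L, sd)
  usable <- which(sds > 0)
  if (length(usable) < ncol(genotypes)) {
    warning(sprintf(
      "%d zero-variance SNP column(s) excluded from screening",
      ncol(genotypes) - length(usable)
    ))
  }
  if (length(usable) == 0L) return(integer(0))
  r <- abs(as.vector(cor(genotypes[, usable, drop = FALSE], exposure)))
  ord <- unname(usable[order(-r, usable)])
  ord[seq_len(min(keep, length(ord)))]
}

#' LASSO instrument selection
#'
#' Fits a cross-validated LASSO of the exposure on pre-screened SNP columns
#' and returns the columns with non-zero coefficients at the CV-error
#' minimizing penalty, together with their penalized coefficient estimates
#' (the per-SNP exposure effects used downstream as composite-instrument
#' weights).  The CV fold assignment is drawn under `seed`, so the whole
#' selection is reproducible.  A single-column input falls back to ordinary
#' least squares.
#'
#' @param exposure numeric vector.
#' @param genotypes_screened matrix of pre-screened columns.
#' @param seed integer seed for the CV fold assignment.
#' @param nfolds number of CV folds.
#' @return List with `selected` (indices into `genotypes_screened`) and
#'   `alpha_hat` (matching coefficient estimates); both empty when the
#'   penalized fit sets every coefficient to zero.
#' @export
lasso_select <- function(exposure, genotypes_screened, seed = 1L, nfolds = 5L) {
  x <- as.matrix(genotypes_screened)
  stopifnot(length(exposure) == nrow(x))
  if (ncol(x) == 1L) {
    fit <- lm.fit(cbind(1, x), exposure)
    a <- fit$coefficients[2L]
    if (!is.finite(a) || a == 0) {
      return(list(selected = integer(0), alpha_hat = numeric(0)))
    }
    return(list(selected = 1L, alpha_hat = unname(a)))
  }
  n <- nrow(x)
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  cvfit <- glmnet::cv.glmnet(x, exposure, alpha = 1, foldid = foldid)
  b <- as.vector(coef(cvfit, s = "lambda.min"))[-1L]
  sel <- which(b != 0)
  list(selected = sel, alpha_hat = b[sel])
}

#' Debiased (desparsified) LASSO instrument selection
#'
#' Computes desparsified-LASSO coefficient estimates with asymptotic
#' per-coefficient p-values (LASSO fit plus a nodewise-LASSO projection
#' correction) and retains the columns with `p <= p_threshold`.  Intended as
#' the selection rule when valid per-SNP p-values are wanted instead of raw
#' penalized coefficients.
#'
#' @inheritParams lasso_select
#' @param p_threshold retention threshold on the per-coefficient p-value.
#' @return List with `selected`, `alpha_hat` (debiased estimates for the
#'   retained columns) and `pvals`.
#' @export
debiased_lasso_select <- function(exposure, genotypes_screened,
                                  p_threshold = 0.05, seed = 1L,
                                  nfolds = 5L) {
  x <- as.matrix(genotypes_screened)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(exposure) == n)
  if (p >= n) {
    stop("screened dimension must be below the sample size; reduce `keep`")
  }
  if (p == 1L) {
    fit <- summary(stats::lm(exposure ~ x))$coefficients
    pv <- fit[2L, 4L]
    sel <- if (pv <= p_threshold) 1L else integer(0)
    return(list(
      selected = sel, alpha_hat = unname(fit[2L, 1L])[seq_along(sel)],
      pvals = unname(pv)[seq_along(sel)]
    ))
  }

  seeds <- derive_seeds(seed, p + 1L)
  foldid <- with_seed(seeds[1L], sample(rep_len(seq_len(nfolds), n)))
  cvfit <- glmnet::cv.glmnet(x, exposure, alpha = 1, foldid = foldid)
  b <- as.vector(coef(cvfit, s = "lambda.min"))
  resid <- exposure - as.vector(cbind(1, x) %*% b)
  s0 <- sum(b[-1L] != 0)
  sigma2 <- sum(resid^2) / max(n - s0 - 1L, 1L)

  xc <- scale(x, center = TRUE, scale = FALSE)
  b_deb <- numeric(p)
  se <- numeric(p)
  for (j in seq_len(p)) {
    zj <- nodewise_residual(xc, j, seeds[j + 1L], nfolds)
    zx <- sum(zj * xc[, j])
    b_deb[j] <- b[j + 1L] + sum(zj * resid) / zx
    se[j] <- sqrt(sigma2 * sum(zj^2)) / abs(zx)
  }
  pv <- 2 * pnorm(-abs(b_deb / se))
  sel <- which(pv <= p_threshold)
  list(selected = sel, alpha_hat = b_deb[sel], pvals = pv[sel])
}

# Residual of the nodewise regression of column j on the remaining columns
# (LASSO with CV-chosen penalty; OLS when only one other column exists).
#' @noRd
nodewise_residual <- function(xc, j, seed, nfolds) {
  n <- nrow(xc)
  others <- xc[, -j, drop = FALSE]
  if (ncol(others) == 1L) {
    fit <- lm.fit(cbind(1, others), xc[, j])
    return(fit$residuals)
  }
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  cvj <- glmnet::cv.glmnet(others, xc[, j], alpha = 1, foldid = foldid)
  xc[, j] - as.vector(stats::predict(cvj, others, s = "lambda.min"))
}

#' Partial F-statistic of one instrument given the others
#'
#' Compares the full model (exposure on all selected instruments plus an
#' intercept) with the reduced model dropping the target column:
#' `F = ((RSS_r - RSS_f) / 1) / (RSS_f / (n - k - 1))`, with `k` the number
#' of predictors in the full model (the classical partial-F convention, under
#' which the partial F of a lone instrument equals the squared t-statistic of
#' its simple-regression slope).  One variable is added at a time, so the
#' numerator degrees of freedom is always 1.
#'
#' @param exposure numeric vector.
#' @param genotypes_selected matrix of the selected instrument columns.
#' @param target column index (into `genotypes_selected`) being tested.
#' @return Object of class `partial_f` with fields `f_value`, `rss_reduced`,
#'   `rss_full`, `n`, `k_full`, `p_added`.
#' @export
partial_f <- function(exposure, genotypes_selected, target) {
  x <- as.matrix(genotypes_selected)
  n <- length(exposure)
  stopifnot(nrow(x) == n, target >= 1L, target <= ncol(x))
  k_full <- ncol(x)
  df_resid <- n - k_full - 1L
  if (df_resid <= 0L) {
    stop("too many instruments for this sample: n - k - 1 <= 0 in the full model")
  }
  rss_full <- ols_rss(exposure, x)
  rss_reduced <- ols_rss(exposure, x[, -target, drop = FALSE])
  f <- max(0, (rss_reduced - rss_full)) / (rss_full / df_resid)
  structure(
    list(
      f_value = f, rss_reduced = rss_reduced, rss_full = rss_full,
      n = n, k_full = k_full, p_added = 1L
    ),
    class = "partial_f"
  )
}

# Partial F of every column at once.  For a full-rank design the drop-one
# partial F equals the squared t-statistic of that coefficient in the full
# model, so one OLS fit yields all values; rank-deficient designs fall back
# to explicit reduced-model fits (a dropped collinear column gives F = 0).
#' @noRd
partial_f_all <- function(exposure, x) {
  x <- as.matrix(x)
  n <- length(exposure)
  m <- ncol(x)
  df_resid <- n - m - 1L
  if (df_resid <= 0L) {
    stop("too many instruments for this sample: n - k - 1 <= 0 in the full model")
  }
  design <- cbind(1, x)
  qx <- qr(design)
  if (qx$rank == ncol(design) &&
      identical(qx$pivot, seq_len(ncol(design)))) {
    fit <- lm.fit(design, exposure)
    sigma2 <- sum(fit$residuals^2) / df_resid
    xtx_inv_diag <- diag(chol2inv(qr.R(qx)))
    tstat <- fit$coefficients / sqrt(sigma2 * xtx_inv_diag)
    return(unname(tstat[-1L]^2))
  }
  vapply(seq_len(m), function(j) partial_f(exposure, x, j)$f_value, numeric(1))
}

#' Classify selected instruments as major or weak
#'
#' Instruments with partial F strictly greater than `f_threshold` are major;
#' the rest are weak and will be consolidated into a composite instrument.
#'
#' @param selection a list with `selected`, `alpha_hat` and `partial_f`
#'   (equal-length vectors), e.g. as produced by [select_ivs()].
#' @param f_threshold major-instrument cutoff (10/30/50 are common choices;
#'   30 is the default).
#' @return Object of class `iv_selection` with `major` and `weak` index
#'   vectors partitioning `selected`.
#' @export
classify_ivs <- function(selection, f_threshold = 30) {
  stopifnot(
    length(selection$selected) == length(selection$alpha_hat),
    length(selection$selected) == length(selection$partial_f)
  )
  is_major <- selection$partial_f > f_threshold
  structure(
    list(
      half_id = selection$half_id %||% NA_integer_,
      selected = selection$selected,
      alpha_hat = selection$alpha_hat,
      partial_f = selection$partial_f,
      major = selection$selected[is_major],
      weak = selection$selected[!is_major],
      alpha_major = selection$alpha_hat[is_major],
      alpha_weak = selection$alpha_hat[!is_major],
      f_threshold = f_threshold
    ),
    class = "iv_selection"
  )
}

#' @export
print.iv_selection <- function(x, ...) {
  cat(sprintf(
    "<iv_selection> %d selected: %d major (partial F > %g), %d weak\n",
    length(x$selected), length(x$major), x$f_threshold, length(x$weak)
  ))
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full instrument-selection pipeline on one (half-)sample
#'
#' Runs SIS screening, penalized selection (LASSO or debiased LASSO),
#' per-instrument partial F-statistics and major/weak classification.
#' Returned indices refer to columns of the original `genotypes` matrix.
#'
#' @param exposure numeric vector.
#' @param genotypes dosage matrix, rows aligned with `exposure`.
#' @param keep SIS retention count; default is half the sample size (capped
#'   at the number of SNPs).
#' @param selector `"lasso"` or `"dlasso"`.
#' @param f_threshold major-instrument partial-F cutoff.
#' @param p_threshold p-value cutoff for the `"dlasso"` selector.
#' @param refit_alpha if `TRUE`, replace the selector's effect estimates by a
#'   post-selection OLS refit on the selected columns.
#' @param seed integer seed controlling CV fold assignments.
#' @param half_id optional label recording which half the selection was
#'   trained on.
#' @return An [classify_ivs()] `iv_selection` object (empty selection yields
#'   zero-length index vectors, not an error).
#' @export
select_ivs <- function(exposure, genotypes, keep = NULL,
                       selector = c("lasso", "dlasso"), f_threshold = 30,
                       p_threshold = 0.05, refit_alpha = FALSE, seed = 1L,
                       half_id = NA_integer_) {
  selector <- match.arg(selector)
  genotypes <- as.matrix(genotypes)
  n <- length(exposure)
  if (is.null(keep)) keep <- max(1L, floor(n / 2))
  keep <- min(keep, ncol(genotypes))

  screened <- sis_screen(exposure, genotypes, keep)
  empty <- classify_ivs(
    list(
      selected = integer(0), alpha_hat = numeric(0),
      partial_f = numeric(0), half_id = half_id
    ),
    f_threshold
  )
  if (length(screened) == 0L) return(empty)

  xs <- genotypes[, screened, drop = FALSE]
  sel <- switch(selector,
    lasso = lasso_select(exposure, xs, seed = seed),
    dlasso = debiased_lasso_select(exposure, xs,
      p_threshold = p_threshold, seed = seed
    )
  )
  if (length(sel$selected) == 0L) return(empty)

  selected <- screened[sel$selected]
  alpha_hat <- sel$alpha_hat
  xsel <- genotypes[, selected, drop = FALSE]
  if (refit_alpha) {
    fit <- lm.fit(cbind(1, xsel), exposure)
    alpha_hat <- unname(fit$coefficients[-1L])
    alpha_hat[is.na(alpha_hat)] <- 0
  }
  fvals <- partial_f_all(exposure, xsel)
  classify_ivs(
    list(
      selected = selected, alpha_hat = alpha_hat, partial_f = fvals,
      half_id = half_id
    ),
    f_threshold
  )
}
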