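# Second-stage causal estimation and comparator estimators: 2SLS, LIML, CFMR.

#' @noRd
new_estimate <- function(beta, se, pval, ci_low, ci_high, method,
                         n_instruments) {
  structure(
    list(
      beta_hat = unname(beta), se = unname(se), pval = unname(pval),
      ci_low = unname(ci_low), ci_high = unname(ci_high), method = method,
      n_instruments = n_instruments
    ),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate:%s> beta=%.4f se=%.4f p=%.3g 95%% CI [%.4f, %.4f] (%d IV)\n",
    x$method, x$beta_hat, x$se, x$pval, x$ci_low, x$ci_high, x$n_instruments
  ))
  invisible(x)
}

#' Second-stage regression on a cross-fitted exposure
#'
#' Continuous outcome: OLS of the outcome on an intercept and the fitted
#' exposure gives `beta_hat = (Xhat' Xhat)^{-1} Xhat' Y` (after centering);
#' the standard error follows the conventional 2SLS variance, with the error
#' variance estimated from residuals computed with the *observed* exposure,
#' `Y - a - X * beta_hat`.  Binary outcome: logistic regression of the
#' outcome on the fitted exposure with a Wald standard error (two-stage
#' predictor substitution).
#'
#' @param outcome,fitted_exposure,observed_exposure aligned numeric vectors.
#' @param outcome_binary logical flag.
#' @param n_instruments recorded in the result (informational).
#' @param method label recorded in the result.
#' @return An `mr_estimate`.
#' @export
tsls_second_stage <- function(outcome, fitted_exposure, observed_exposure,
                              outcome_binary = FALSE, n_instruments = NA_integer_,
                              method = "2sls") {
  n <- length(outcome)
  stopifnot(
    length(fitted_exposure) == n, length(observed_exposure) == n
  )
  if (sd(fitted_exposure) == 0) {
    stop("fitted exposure is constant: no identification")
  }
  if (outcome_binary) {
    fit <- stats::glm(outcome ~ fitted_exposure, family = stats::binomial())
    sm <- summary(fit)$coefficients
    beta <- sm[2L, 1L]
    se <- sm[2L, 2L]
    pval <- sm[2L, 4L]
    crit <- qnorm(0.975)
    return(new_estimate(
      beta, se, pval, beta - crit * se, beta + crit * se, method,
      n_instruments
    ))
  }
  z <- cbind(1, fitted_exposure)
  ztz_inv <- solve(crossprod(z))
  coefs <- ztz_inv %*% crossprod(z, outcome)
  beta <- coefs[2L, 1L]
  resid_struct <- outcome - coefs[1L, 1L] - observed_exposure * beta
  df <- n - 2L
  sigma2 <- sum(resid_struct^2) / df
  se <- sqrt(sigma2 * ztz_inv[2L, 2L])
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  crit <- qt(0.975, df)
  new_estimate(
    beta, se, pval, beta - crit * se, beta + crit * se, method, n_instruments
  )
}

#' Two-stage least squares with explicit instruments
#'
#' Standard 2SLS: first-stage OLS of the exposure on all given instrument
#' columns, then [tsls_second_stage()] on the fitted values.  All instruments
#' enter individually; no major/weak differentiation.
#'
#' @param data an [mr_data()] object.
#' @param instrument_columns SNP column indices to use as instruments.
#' @return An `mr_estimate`.
#' @export
tsls_full <- function(data, instrument_columns) {
  stopifnot(inherits(data, "mrdata"), length(instrument_columns) >= 1L)
  n <- length(data$exposure)
  m <- length(instrument_columns)
  if (m + 1L >= n) stop("more instruments (plus intercept) than samples")
  g <- data$genotypes[, instrument_columns, drop = FALSE]
  xhat <- fit_first_stage(data$exposure, g, NULL)
  tsls_second_stage(
    data$outcome, xhat, data$exposure, data$outcome_binary,
    n_instruments = m, method = "2sls"
  )
}

#' Limited-information maximum likelihood (LIML) estimator
#'
#' k-class estimator with kappa set to the smallest eigenvalue of the LIML
#' eigenproblem on the centered `(Y, X)` cross-product matrices with and
#' without projection on the instruments; the intercept is partialled out
#' first.  The standard error uses the k-class asymptotic variance.  LIML is
#' defined for continuous outcomes only.
#'
#' @param data an [mr_data()] object with a continuous outcome.
#' @param instrument_columns SNP column indices.
#' @param kappa optional override of the k-class parameter (`kappa = 1`
#'   reproduces 2SLS exactly; the default `NULL` uses the LIML eigenvalue).
#' @return An `mr_estimate`.
#' @export
liml <- function(data, instrument_columns, kappa = NULL) {
  stopifnot(inherits(data, "mrdata"), length(instrument_columns) >= 1L)
  if (data$outcome_binary) {
    stop("LIML requires a continuous outcome; it is not defined for binary outcomes")
  }
  n <- length(data$exposure)
  m <- length(instrument_columns)
  if (m + 1L >= n) stop("more instruments (plus intercept) than samples")

  y <- data$outcome - mean(data$outcome)
  x <- data$exposure - mean(data$exposure)
  z <- scale(data$genotypes[, instrument_columns, drop = FALSE],
    center = TRUE, scale = FALSE
  )
  w <- cbind(y, x)
  qz <- qr(z)
  pw <- qr.fitted(qz, w) # projection of (y, x) on the instrument span
  a <- crossprod(w)
  b <- a - crossprod(w, pw) # W' M_Z W
  if (is.null(kappa)) {
    kappa <- min(Re(eigen(solve(b, a), only.values = TRUE)$values))
  }

  mx <- x - qr.fitted(qz, x)
  my <- y - qr.fitted(qz, y)
  denom <- sum(x * x) - kappa * sum(x * mx)
  numer <- sum(x * y) - kappa * sum(x * my)
  if (abs(denom) < .Machine$double.eps * n) {
    stop("k-class denominator is numerically zero: instruments uninformative")
  }
  beta <- numer / denom
  df <- n - 2L
  sigma2 <- sum((y - x * beta)^2) / df
  se <- sqrt(sigma2 / denom)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  crit <- qt(0.975, df)
  new_estimate(
    beta, se, pval, beta - crit * se, beta + crit * se, "liml", m
  )
}

#' Cross-fitted MR (CFMR) comparator
#'
#' Splits the sample into `k_folds` folds; for each fold, a SIS + LASSO
#' exposure-prediction model is fitted on the complement and its prediction
#' on the fold becomes that fold's segment of the single cross-fitted
#' instrument (a polygenic-score-like instrument).  The stacked instrument
#' then drives a just-identified 2SLS fit of the outcome on the exposure over
#' the full sample.  A fold whose selection is empty contributes the
#' intercept-only prediction (a constant); if every fold is empty the
#' estimator fails.
#'
#' @param data an [mr_data()] object.
#' @param k_folds number of folds (>= 2; 10 is conventional).
#' @param keep SIS retention count per training complement (default: half the
#'   complement's size).
#' @param seed integer seed (fold assignment and CV folds).
#' @return An `mr_estimate` with the cross-fitted instrument attached as
#'   attribute `cfi`.
#' @export
cfmr <- function(data, k_folds = 10L, keep = NULL, seed = 1L) {
  stopifnot(inherits(data, "mrdata"), k_folds >= 2L)
  n <- length(data$exposure)
  if (n < 2L * k_folds) stop("need at least 2 samples per fold")
  fold_of <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  fold_seeds <- derive_seeds(seed, k_folds)

  cfi <- rep(NA_real_, n)
  any_selected <- FALSE
  n_selected <- numeric(k_folds)
  for (k in seq_len(k_folds)) {
    idx <- which(fold_of == k)
    train <- which(fold_of != k)
    x_tr <- data$exposure[train]
    g_tr <- data$genotypes[train, , drop = FALSE]
    kp <- if (is.null(keep)) max(1L, floor(length(train) / 2)) else keep
    screened <- sis_screen(x_tr, g_tr, min(kp, ncol(g_tr)))
    sel <- if (length(screened) == 0L) {
      list(selected = integer(0), alpha_hat = numeric(0))
    } else {
      lasso_select(x_tr, g_tr[, screened, drop = FALSE], seed = fold_seeds[k])
    }
    if (length(sel$selected) == 0L) {
      cfi[idx] <- mean(x_tr) # intercept-only prediction
      next
    }
    any_selected <- TRUE
    n_selected[k] <- length(sel$selected)
    cols <- screened[sel$selected]
    intercept <- mean(x_tr) -
      sum(colMeans(g_tr[, cols, drop = FALSE]) * sel$alpha_hat)
    cfi[idx] <- intercept +
      as.vector(data$genotypes[idx, cols, drop = FALSE] %*% sel$alpha_hat)
  }
  if (!any_selected) stop("CFMR failed: empty IV selection in every fold")
  if (sd(cfi) == 0) stop("CFMR instrument is constant: no identification")

  xhat <- fit_first_stage(data$exposure, cfi, NULL)
  est <- tsls_second_stage(
    data$outcome, xhat, data$exposure, data$outcome_binary,
    n_instruments = 1L, method = "cfmr"
  )
  attr(est, "cfi") <- cfi
  attr(est, "per_fold_n_selected") <- n_selected
  est
}
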