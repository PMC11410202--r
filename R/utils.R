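# Internal helpers: seeding, logging, small linear-algebra utilities.

#' @noRd
msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}

# Derive a stream of child seeds from one master seed.  Drawing the seeds
# from a seeded RNG (rather than master + index arithmetic) keeps streams
# for different cells/replicates disjoint with overwhelming probability and
# keeps every seed inside the 32-bit integer range.
#' @noRd
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' @noRd
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

#' @noRd
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user simulations.
#' @noRd
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Residual sum of squares of y regressed on (intercept + x), via QR.
#' @noRd
ols_rss <- function(y, x = NULL) {
  n <- length(y)
  design <- if (is.null(x) || ncol(as.matrix(x)) == 0L) {
    matrix(1, n, 1L)
  } else {
    cbind(1, as.matrix(x))
  }
  fit <- lm.fit(design, y)
  sum(fit$residuals^2)
}
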