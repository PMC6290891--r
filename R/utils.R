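#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition so callers/tests can match on error type
#' @noRd
fc_stop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "fconn_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Nearest positive-semidefinite projection by eigenvalue clipping
#'
#' Clips negative eigenvalues at zero and rescales to unit diagonal, the
#' standard repair for mildly indefinite correlation matrices.
#'
#' @param x symmetric matrix.
#' @return symmetric PSD matrix with unit diagonal.
#' @keywords internal
nearest_psd <- function(x) {
  x <- (x + t(x)) / 2
  e <- eigen(x, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  y <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(y), .Machine$double.eps))
  y <- y / tcrossprod(d)
  y <- (y + t(y)) / 2
  diag(y) <- 1
  y
}

#' Symmetric matrix square root via eigendecomposition
#' @noRd
sqrtm_sym <- function(x) {
  e <- eigen((x + t(x)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Derive per-unit RNG sub-seeds from one master seed
#'
#' Deterministic regardless of how many draws each consumer makes:
#' the master stream is used only to draw one 31-bit seed per unit.
#' @noRd
derive_seeds <- function(master_seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

#' Exact binomial 95 percent confidence interval (Clopper-Pearson)
#' @noRd
binom_ci95 <- function(x, n) {
  lo <- if (x == 0) 0 else stats::qbeta(0.025, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(0.975, x + 1, n - x)
  c(lo, hi)
}
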