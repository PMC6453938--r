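#' Logit and inverse-logit
#'
#' Thin wrappers used throughout the vital-rate machinery. `logit()` maps
#' probabilities to the real line, `inv_logit()` maps back; both are
#' vectorised.
#'
#' @param p probabilities in (0, 1).
#' @param x real values.
#' @return numeric vector.
#' @keywords internal
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @keywords internal
inv_logit <- function(x) stats::plogis(x)

#' Clamp rates away from the unit-interval boundary
#'
#' Rates exactly 0 or 1 have infinite logits; posterior-mean panels can hit
#' the boundary through rounding. Values are clamped to
#' `[eps, 1 - eps]` before the logit transform.
#'
#' @param p numeric vector of rates.
#' @param eps boundary margin (default 1e-6).
#' @return clamped vector.
#' @keywords internal
clamp_rates <- function(p, eps = 1e-6) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Project a symmetric matrix to the nearest positive semi-definite matrix
#'
#' Eigenvalue clipping at zero: negative eigenvalues (sampling noise in a
#' covariance estimate) are set to 0 and the matrix reassembled. The input is
#' symmetrised first.
#'
#' @param m square numeric matrix.
#' @return symmetric PSD matrix of the same dimension.
#' @keywords internal
nearest_psd <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values >= 0)) return(m)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
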