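# Small shared numerical helpers.

#' Logit and inverse-logit transforms
#'
#' Methylation beta values live in (0,1); planted effects are applied on the
#' logit scale so the inverse transform keeps simulated betas in range.
#'
#' @param x numeric vector or matrix.
#' @return transformed values.
#' @keywords internal
logit <- function(x) log(x / (1 - x))

#' @rdname logit
#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

# Clip p-values away from 0 and 1 before probit transformation.
# Lower bound keeps qnorm finite at double precision.
clip_p <- function(p, lo = 1e-300, hi = 1 - 1e-16) {
  pmin(pmax(p, lo), hi)
}

# Moore-Penrose pseudo-inverse via SVD; used where an implied covariance is
# legitimately singular (e.g. factor scoring with zero unique variances).
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Pearson correlation p-value (two-sided, t reference), vectorised over r.
cor_pval <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
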