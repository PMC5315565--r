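# Reference-based cell-composition estimation (constrained projection).
#
# For each sample, proportions pi minimize ||beta_panel - R pi||^2 subject
# to pi >= 0 and, depending on the chosen constraint, sum(pi) <= 1 or
# sum(pi) = 1. The cited deconvolution approach projects onto the
# non-negative orthant without forcing the simplex, so sum <= 1 is the
# default. The quadratic program is solved exactly by enumerating active
# sets: with K reference cell types there are 2^K candidate zero-patterns
# (times the sum-constraint on/off), each a small equality-constrained
# least-squares solve; the feasible candidate with the smallest objective
# is the global optimum. K is small (five blood cell types in the
# motivating design), so enumeration is both exact and cheap.

#' Estimate cell-type proportions by constrained projection
#'
#' @param M a \code{\link{methylome}} object or a samples x probes beta
#'   matrix with probe ids as column names.
#' @param panel reference panel: data.frame with a \code{probe_id} column
#'   plus one column of mean beta values per cell type, or an equivalent
#'   matrix with probe-id rownames.
#' @param constraint \code{"sum_le_1"} (default, matches the reference
#'   method's projection) or \code{"sum_eq_1"}.
#' @return matrix (samples x cell types) of proportions, each >= 0, row
#'   sums bounded by 1 (equal to 1 under \code{"sum_eq_1"}); cell types in
#'   panel column order.
#' @export
estimate_proportions <- function(M, panel, constraint = c("sum_le_1", "sum_eq_1")) {
  constraint <- match.arg(constraint)
  beta <- if (inherits(M, "methylome")) M$beta else M
  if (is.data.frame(panel)) {
    R <- as.matrix(panel[, setdiff(names(panel), "probe_id"), drop = FALSE])
    rownames(R) <- panel$probe_id
  } else {
    R <- as.matrix(panel)
  }
  if (ncol(R) < 2) stop("need at least 2 reference cell types")
  if (nrow(R) <= ncol(R)) stop("need more panel probes than cell types")
  miss <- setdiff(rownames(R), colnames(beta))
  if (length(miss) > 0)
    stop("panel probes absent from beta matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    dep <- colnames(R)[setdiff(seq_len(ncol(R)), qrR$pivot[seq_len(qrR$rank)])]
    stop("reference panel is rank-deficient; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  Y <- t(beta[, rownames(R), drop = FALSE])  # probes x samples
  out <- t(apply(Y, 2, .project_simplex, R = R, constraint = constraint))
  colnames(out) <- colnames(R)
  rownames(out) <- rownames(beta)
  out
}

# Exact constrained least squares for one sample by active-set enumeration.
.project_simplex <- function(y, R, constraint) {
  K <- ncol(R)
  G <- crossprod(R)        # K x K
  h <- crossprod(R, y)
  best <- NULL
  best_obj <- Inf
  tol <- 1e-9
  sum_opts <- if (constraint == "sum_eq_1") TRUE else c(FALSE, TRUE)
  for (mask in 0:(2^K - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) == 0)
    if (length(free) == 0) {
      cand_list <- if (constraint == "sum_eq_1") NULL else list(numeric(K))
      for (cand in cand_list) {
        obj <- sum((y - R %*% cand)^2)
        if (obj < best_obj - 1e-15) { best_obj <- obj; best <- cand }
      }
      next
    }
    for (sum_active in sum_opts) {
      nf <- length(free)
      x <- rep(0, K)
      if (sum_active) {
        A <- rbind(cbind(2 * G[free, free, drop = FALSE], rep(1, nf)),
                   c(rep(1, nf), 0))
        b <- c(2 * h[free], 1)
        sol <- tryCatch(solve(A, b), error = function(e) NULL)
        if (is.null(sol)) next
        x[free] <- sol[seq_len(nf)]
      } else {
        sol <- tryCatch(solve(G[free, free, drop = FALSE], h[free]),
                        error = function(e) NULL)
        if (is.null(sol)) next
        x[free] <- sol
      }
      if (any(x < -tol)) next
      if (sum(x) > 1 + tol) next
      x <- pmax(x, 0)
      obj <- sum((y - R %*% x)^2)
      if (obj < best_obj - 1e-15) { best_obj <- obj; best <- x }
    }
  }
  if (is.null(best)) stop("no feasible solution found (degenerate panel?)")
  best
}
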