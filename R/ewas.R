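# Probe-wise epigenome-wide association testing.
#
# Each probe's beta values are the regression response, the phenotype (e.g.
# the substance-use liability score, or prenatal smoking for the biological
# validation analysis) the predictor, adjusting for sex and estimated
# cell-type proportions. All probes share one design matrix, so the
# per-probe ordinary least squares fits are computed in a single QR
# decomposition. The standardized coefficient is
# b * SD(predictor) / SD(beta_probe), a correlation-scale quantity.

#' Remove probes flagged by array quality control
#'
#' Probes are dropped when cross-reactive, used for sample identification
#' on the array (control probes), or carrying a common polymorphism
#' (MAF > 5\%) at the single-base extension site. Order is preserved.
#'
#' @param annotation probe annotation data.frame with logical columns
#'   \code{cross_reactive}, \code{control_probe}, \code{snp_at_sbe}.
#' @return character vector of retained probe ids.
#' @export
filter_probes <- function(annotation) {
  need <- c("cross_reactive", "control_probe", "snp_at_sbe")
  if (!all(need %in% names(annotation)))
    stop("annotation missing flag columns: ",
         paste(setdiff(need, names(annotation)), collapse = ", "))
  drop <- annotation$cross_reactive | annotation$control_probe |
    annotation$snp_at_sbe
  as.character(annotation$probe_id[!drop])
}

#' Probe-wise covariate-adjusted association analysis
#'
#' @param M \code{\link{methylome}} object, or samples x probes matrix (an
#'   annotation is then optional).
#' @param outcome numeric predictor of interest, one value per sample (the
#'   phenotype; methylation is the response).
#' @param covariates data.frame/matrix of adjustment covariates (e.g. sex
#'   and five cell-type proportions), or NULL.
#' @param probes optional probe ids to restrict to (e.g. QC-filtered set).
#' @param m_total number of tests for the FDR correction; defaults to the
#'   number of probes analysed.
#' @return an EWAS table (class \code{ewas_table}): one row per probe with
#'   \code{std_beta}, \code{se}, \code{t}, \code{p}, \code{q},
#'   \code{n_used}, \code{direction} ("hypomethylated" when std_beta < 0),
#'   and a \code{flag} for degenerate (zero-variance) probes, which carry
#'   missing p and q.
#' @export
run_ewas <- function(M, outcome, covariates = NULL, probes = NULL,
                     m_total = NULL) {
  beta <- if (inherits(M, "methylome")) M$beta else M
  ann <- if (inherits(M, "methylome")) M$annotation else NULL
  if (!is.null(probes)) {
    miss <- setdiff(probes, colnames(beta))
    if (length(miss) > 0)
      stop("probes absent from matrix: ", paste(utils::head(miss, 5),
                                                collapse = ", "))
    beta <- beta[, probes, drop = FALSE]
  }
  n_all <- nrow(beta)
  X <- cbind(`(Intercept)` = 1, outcome = outcome)
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    X <- cbind(X, cv)
  }
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  Y <- beta[keep, , drop = FALSE]
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1) stop("too few complete cases for the design")
  if (stats::sd(X[, "outcome"]) == 0) stop("predictor has zero variance")

  qx <- qr(X)
  if (qx$rank < k) {
    ## estimated cell proportions can sum to exactly 1 for every sample,
    ## aliasing the intercept; drop redundant covariate columns (never the
    ## intercept or the predictor) and refit
    keep_cols <- sort(qx$pivot[seq_len(qx$rank)])
    if (!all(1:2 %in% keep_cols))
      stop("design matrix is rank deficient in the predictor")
    dropped <- colnames(X)[setdiff(seq_len(k), keep_cols)]
    warning("dropping collinear covariate(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep_cols, drop = FALSE]
    k <- ncol(X)
    qx <- qr(X)
  }
  coefs <- qr.coef(qx, Y)                      # k x p
  fitted <- X %*% coefs
  rss <- colSums((Y - fitted)^2)
  dfres <- n - k
  sigma2 <- rss / dfres
  XtX_inv <- matrix(0, k, k)
  XtX_inv[qx$pivot, qx$pivot] <- chol2inv(qr.R(qx))  # undo any qr pivoting
  v_out <- XtX_inv[2, 2]
  b <- coefs["outcome", ]
  se <- sqrt(sigma2 * v_out)
  sd_y <- apply(Y, 2, stats::sd)
  degenerate <- sd_y == 0
  tval <- b / se
  pval <- 2 * stats::pt(-abs(tval), df = dfres)
  std_beta <- b * stats::sd(X[, "outcome"]) / ifelse(degenerate, NA, sd_y)
  tval[degenerate] <- NA; pval[degenerate] <- NA; se[degenerate] <- NA

  m <- m_total %||% sum(!degenerate)
  q <- rep(NA_real_, length(pval))
  q[!degenerate] <- bh_adjust(pval[!degenerate], m_total = m)

  ids <- colnames(beta)
  tab <- data.frame(
    probe_id = ids,
    gene = if (!is.null(ann)) ann$gene[match(ids, ann$probe_id)] else NA,
    chrom = if (!is.null(ann)) ann$chrom[match(ids, ann$probe_id)] else NA,
    position = if (!is.null(ann)) ann$pos[match(ids, ann$probe_id)] else NA,
    std_beta = std_beta, se = se, t = tval, p = pval, q = q,
    n_used = n,
    direction = ifelse(is.na(std_beta), NA,
                       ifelse(std_beta < 0, "hypomethylated",
                              "hypermethylated")),
    flag = ifelse(degenerate, "zero_variance", ""),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  attr(tab, "m_total") <- m
  attr(tab, "n_complete") <- n
  class(tab) <- c("ewas_table", "data.frame")
  tab
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Supports adjusting a sub-vector of p-values against a larger family of
#' \code{m_total} tests (ranks are taken within the supplied vector, the
#' multiplier is \code{m_total}), as needed when correcting a printed
#' top-table against the full epigenome-wide test count.
#'
#' @param p numeric vector of p-values in [0,1].
#' @param m_total total number of tests (>= \code{length(p)}).
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(p, m_total = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  if (m_total < length(p)) stop("m_total must be >= length(p)")
  stats::p.adjust(p, method = "BH", n = m_total)
}

#' Select differentially methylated probes at an FDR threshold
#'
#' @param ewas an \code{ewas_table}.
#' @param q_threshold FDR threshold (default 0.05).
#' @return a \code{dmp_set}: data.frame of selected probes sorted by p
#'   ascending (ties broken by probe id), carrying the discovery
#'   standardized betas as score weights.
#' @export
select_dmps <- function(ewas, q_threshold = 0.05) {
  keep <- !is.na(ewas$q) & ewas$q < q_threshold
  d <- ewas[keep, c("probe_id", "std_beta", "p", "q"), drop = FALSE]
  d <- d[order(d$p, d$probe_id), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "q_threshold") <- q_threshold
  attr(d, "m_total") <- attr(ewas, "m_total")
  class(d) <- c("dmp_set", "data.frame")
  d
}

#' Re-test discovery DMPs at a later timepoint (follow-forward)
#'
#' Runs the same covariate-adjusted regression on the restricted probe set
#' at the second timepoint; the FDR correction is over the number of DMPs
#' only. Probes absent at the later timepoint are listed and excluded.
#'
#' @param dmps a \code{dmp_set} from the discovery timepoint.
#' @param M2 methylome at the later timepoint.
#' @param outcome,covariates as in \code{\link{run_ewas}}.
#' @param q_threshold replication threshold.
#' @return \code{ewas_table} restricted to the DMPs, with attributes
#'   \code{n_replicated} (q < threshold), \code{nominal} (probe ids with
#'   unadjusted p < 0.05), and \code{missing_probes}.
#' @export
follow_forward <- function(dmps, M2, outcome, covariates = NULL,
                           q_threshold = 0.05) {
  beta2 <- if (inherits(M2, "methylome")) M2$beta else M2
  present <- intersect(dmps$probe_id, colnames(beta2))
  missing <- setdiff(dmps$probe_id, present)
  if (length(present) == 0) stop("no discovery probes present at timepoint 2")
  tab <- run_ewas(M2, outcome, covariates, probes = present,
                  m_total = length(present))
  attr(tab, "n_replicated") <- sum(tab$q < q_threshold, na.rm = TRUE)
  attr(tab, "nominal") <- tab$probe_id[!is.na(tab$p) & tab$p < 0.05]
  attr(tab, "missing_probes") <- missing
  tab
}

#' Per-probe cross-timepoint autocorrelation
#'
#' Pearson correlation, per probe, of methylation at the two timepoints
#' over shared samples, with two-sided p-values and the summary reported in
#' the field's (r_max, r_min, mean |r|, n significant) form.
#'
#' @param M1,M2 methylome objects (or matrices) sharing samples.
#' @param probes probe ids to correlate (e.g. the DMP set).
#' @return list with \code{per_probe} (data.frame probe_id, r, p) and
#'   \code{summary} (r_max, r_min, mean_abs_r, n_sig at p < 0.05).
#' @export
probe_autocorrelation <- function(M1, M2, probes) {
  b1 <- if (inherits(M1, "methylome")) M1$beta else M1
  b2 <- if (inherits(M2, "methylome")) M2$beta else M2
  shared <- intersect(rownames(b1), rownames(b2))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  x1 <- b1[shared, probes, drop = FALSE]
  x2 <- b2[shared, probes, drop = FALSE]
  r <- vapply(seq_along(probes), function(j)
    stats::cor(x1[, j], x2[, j]), 0)
  p <- cor_pval(r, length(shared))
  per <- data.frame(probe_id = probes, r = r, p = p,
                    stringsAsFactors = FALSE)
  list(per_probe = per,
       summary = c(r_max = max(r), r_min = min(r),
                   mean_abs_r = mean(abs(r)), n_sig = sum(p < 0.05)))
}

#' Within-timepoint co-methylation structure over a probe set
#'
#' @param M methylome (or matrix).
#' @param probes probe ids (>= 2).
#' @return list with the pairwise Pearson matrix \code{R}, BH-adjusted
#'   \code{q} per pair (over all n(n-1)/2 pairs), and a summary
#'   (\code{pct_sig} of pairs at q < 0.05, \code{r_max}, \code{r_min}
#'   among off-diagonal entries).
#' @export
comethylation_structure <- function(M, probes) {
  beta <- if (inherits(M, "methylome")) M$beta else M
  if (length(probes) < 2) stop("need at least 2 probes")
  X <- beta[, probes, drop = FALSE]
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant probe in set")
  R <- stats::cor(X)
  lower <- R[lower.tri(R)]
  pv <- cor_pval(lower, nrow(X))
  qv <- bh_adjust(pv)
  Q <- matrix(NA_real_, nrow(R), ncol(R), dimnames = dimnames(R))
  Q[lower.tri(Q)] <- qv
  Q[upper.tri(Q)] <- t(Q)[upper.tri(Q)]
  list(R = R, q = Q,
       summary = c(pct_sig = 100 * mean(qv < 0.05),
                   r_max = max(lower), r_min = min(lower)))
}

#' Similarity of two co-methylation structures
#'
#' Pearson correlation of the vectorized lower triangles, with a seeded
#' Mantel-style permutation p-value (probes permuted jointly in the second
#' matrix) as a secondary output.
#'
#' @param C1,C2 correlation matrices over the same probes.
#' @param n_perm number of permutations for the Mantel test.
#' @param seed RNG seed for the permutations.
#' @return list with \code{similarity} and \code{mantel_p}.
#' @export
compare_structures <- function(C1, C2, n_perm = 999, seed = 1) {
  stopifnot(all(dim(C1) == dim(C2)))
  v1 <- C1[lower.tri(C1)]
  obs <- stats::cor(v1, C2[lower.tri(C2)])
  set.seed(seed)
  n <- nrow(C2)
  perm_stats <- replicate(n_perm, {
    idx <- sample.int(n)
    Cp <- C2[idx, idx]
    stats::cor(v1, Cp[lower.tri(Cp)])
  })
  mantel_p <- (1 + sum(perm_stats >= obs)) / (n_perm + 1)
  list(similarity = obs, mantel_p = mantel_p)
}
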