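# Path-analytic mediation: prenatal exposures -> methylation risk score ->
# substance-use liability.
#
# The recursive linear path model estimated by ML is equivalent to two
# ordinary least-squares regressions: the mediator on the exposures
# (a-paths) and the outcome on the mediator plus exposures (b-path and
# direct c'-paths). Each exposure's indirect effect is the product a_k * b.
# Inference for the indirect effects uses the nonparametric case-resampling
# bootstrap with percentile confidence intervals; Wald p-values
# (estimate / SE against the normal) accompany the CIs, mirroring the joint
# reporting convention of the field.

#' Fit the exposure -> mediator -> outcome path model (point estimates)
#'
#' @param exposures matrix or data.frame of exposure columns.
#' @param mediator numeric vector (e.g. the methylation risk score).
#' @param outcome numeric vector (e.g. the liability factor score).
#' @param standardize z-score mediator and outcome before fitting
#'   (standardized coefficients are always reported alongside; this flag
#'   controls the scale of the headline estimates). Default FALSE so the
#'   headline coefficients are unstandardized.
#' @return object of class \code{mediation_fit}: data.frames \code{a}
#'   (a-paths), \code{bc} (b and c'-paths), \code{indirect}
#'   (a_k * b with delta-method SE and Wald p), \code{total} (total
#'   effects), plus \code{n} and the complete-case index.
#' @export
fit_path_model <- function(exposures, mediator, outcome, standardize = FALSE) {
  X <- as.matrix(as.data.frame(exposures))
  storage.mode(X) <- "double"
  ok <- stats::complete.cases(X, mediator, outcome)
  X <- X[ok, , drop = FALSE]
  m <- mediator[ok]; y <- outcome[ok]
  n <- nrow(X)
  if (n <= ncol(X) + 3) stop("too few complete cases for the path model")
  kap <- kappa(cbind(1, X), exact = TRUE)
  if (kap > 1e8) stop("exposures are (near-)collinear; condition number ",
                      format(kap, digits = 3))
  if (standardize) {
    m <- as.numeric(scale(m)); y <- as.numeric(scale(y))
  }

  fa <- stats::lm.fit(cbind(`(Intercept)` = 1, X), m)
  fb <- stats::lm.fit(cbind(`(Intercept)` = 1, mediator = m, X), y)
  a_tab <- .ols_table(cbind(1, X), m, fa)[-1, , drop = FALSE]
  bc_tab <- .ols_table(cbind(1, m, X), y, fb)[-1, , drop = FALSE]
  rownames(a_tab) <- colnames(X)
  rownames(bc_tab) <- c("mediator", colnames(X))

  b_est <- bc_tab["mediator", "est"]
  b_se <- bc_tab["mediator", "se"]
  indirect <- data.frame(
    exposure = colnames(X),
    a = a_tab[, "est"], b = b_est,
    est = a_tab[, "est"] * b_est,
    se = sqrt(a_tab[, "est"]^2 * b_se^2 + b_est^2 * a_tab[, "se"]^2),
    stringsAsFactors = FALSE
  )
  indirect$z <- indirect$est / indirect$se
  indirect$p <- 2 * stats::pnorm(-abs(indirect$z))

  ## total effects (outcome on exposures alone); identity: total = c' + a*b
  ft <- stats::lm.fit(cbind(1, X), y)
  tot <- .ols_table(cbind(1, X), y, ft)[-1, , drop = FALSE]

  ## standardized solution (all variables z-scored)
  sa <- a_tab[, "est"] * apply(X, 2, stats::sd) / stats::sd(m)
  sb <- b_est * stats::sd(m) / stats::sd(y)
  scp <- bc_tab[-1, "est"] * apply(X, 2, stats::sd) / stats::sd(y)

  fit <- list(
    a = data.frame(exposure = colnames(X), est = a_tab[, "est"],
                   se = a_tab[, "se"], p = a_tab[, "p"], std = sa,
                   stringsAsFactors = FALSE),
    bc = data.frame(term = rownames(bc_tab), est = bc_tab[, "est"],
                    se = bc_tab[, "se"], p = bc_tab[, "p"],
                    std = c(sb, scp), stringsAsFactors = FALSE),
    indirect = indirect,
    total = data.frame(exposure = colnames(X), est = tot[, "est"],
                       se = tot[, "se"], p = tot[, "p"],
                       stringsAsFactors = FALSE),
    n = n, standardize = standardize, complete_cases = which(ok)
  )
  class(fit) <- "mediation_fit"
  fit
}

# Coefficient table for an lm.fit result.
.ols_table <- function(Xmat, y, fit) {
  res <- y - Xmat %*% fit$coefficients
  dfres <- nrow(Xmat) - ncol(Xmat)
  s2 <- sum(res^2) / dfres
  XtXi <- chol2inv(chol(crossprod(Xmat)))
  se <- sqrt(s2 * diag(XtXi))
  tv <- fit$coefficients / se
  cbind(est = fit$coefficients, se = se,
        p = 2 * stats::pt(-abs(tv), dfres))
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Path model, n = %d (%s)\n", x$n,
              if (x$standardize) "mediator/outcome z-scored" else "raw scale"))
  cat("Indirect effects (a_k * b):\n")
  print(x$indirect[, c("exposure", "est", "se", "p")], row.names = FALSE)
  invisible(x)
}

#' Bootstrap percentile confidence intervals for all paths
#'
#' Nonparametric case-resampling bootstrap of the full path model.
#' Replicate estimates are stored summary-only (mean, SD, quantiles). A
#' degenerate resample (singular fit) is redrawn and counted.
#'
#' @param exposures,mediator,outcome as in \code{\link{fit_path_model}}.
#' @param B number of bootstrap replicates (>= 100; the motivating design
#'   used 10,000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the same seed reproduces the CIs exactly.
#' @param standardize passed to \code{\link{fit_path_model}}.
#' @return \code{mediation_fit} augmented with \code{ci}: a data.frame of
#'   percentile intervals (term, est, se_boot, lo, hi) for every a-path,
#'   the b-path, every c'-path and every indirect effect; plus \code{B},
#'   \code{seed}, \code{n_redrawn}.
#' @export
bootstrap_ci <- function(exposures, mediator, outcome, B = 1000,
                         level = 0.95, seed = 1, standardize = FALSE) {
  stopifnot(B >= 100)
  fit <- fit_path_model(exposures, mediator, outcome,
                        standardize = standardize)
  X <- as.matrix(as.data.frame(exposures))
  ok <- fit$complete_cases
  X <- X[ok, , drop = FALSE]
  m <- mediator[ok]; y <- outcome[ok]
  n <- length(m)
  kx <- ncol(X)
  terms <- c(paste0("a_", colnames(X)), "b",
             paste0("cprime_", colnames(X)),
             paste0("indirect_", colnames(X)))

  one_rep <- function(idx) {
    Xb <- X[idx, , drop = FALSE]
    mb <- m[idx]; yb <- y[idx]
    if (standardize) {
      mb <- as.numeric(scale(mb)); yb <- as.numeric(scale(yb))
    }
    Da <- cbind(1, Xb)
    Db <- cbind(1, mb, Xb)
    ca <- tryCatch(qr.coef(qr(Da), mb), error = function(e) NULL)
    cb <- tryCatch(qr.coef(qr(Db), yb), error = function(e) NULL)
    if (is.null(ca) || is.null(cb) || anyNA(ca) || anyNA(cb)) return(NULL)
    a <- ca[-1]; b <- cb[2]; cp <- cb[-(1:2)]
    c(a, b, cp, a * b)
  }

  set.seed(seed)
  reps <- matrix(NA_real_, B, length(terms))
  n_redrawn <- 0L
  for (i in seq_len(B)) {
    repeat {
      v <- one_rep(sample.int(n, n, replace = TRUE))
      if (!is.null(v)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100 * B) stop("bootstrap resamples persistently singular")
    }
    reps[i, ] <- v
  }
  alpha <- (1 - level) / 2
  qs <- t(apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                type = 7))
  est <- c(fit$a$est, fit$bc$est[fit$bc$term == "mediator"],
           fit$bc$est[fit$bc$term != "mediator"], fit$indirect$est)
  fit$ci <- data.frame(term = terms, est = est,
                       se_boot = apply(reps, 2, stats::sd),
                       lo = qs[, 1], hi = qs[, 2],
                       stringsAsFactors = FALSE)
  fit$boot_summary <- data.frame(term = terms,
                                 mean = colMeans(reps),
                                 sd = apply(reps, 2, stats::sd))
  fit$B <- B
  fit$level <- level
  fit$seed <- seed
  fit$n_redrawn <- n_redrawn
  fit
}

#' Mediation refit with each first-order substance factor as outcome
#'
#' @param exposures,mediator as in \code{\link{fit_path_model}}.
#' @param first_order_scores data.frame with one column per substance
#'   factor (tobacco, cannabis, alcohol).
#' @param B,level,seed bootstrap settings; \code{B = NULL} skips the
#'   bootstrap and returns point fits only.
#' @return named list of \code{mediation_fit} objects, one per substance.
#' @export
per_substance_mediation <- function(exposures, mediator, first_order_scores,
                                    B = NULL, level = 0.95, seed = 1) {
  first_order_scores <- as.data.frame(first_order_scores)
  fits <- lapply(names(first_order_scores), function(s) {
    y <- first_order_scores[[s]]
    if (is.null(B)) fit_path_model(exposures, mediator, y)
    else bootstrap_ci(exposures, mediator, y, B = B, level = level,
                      seed = seed)
  })
  names(fits) <- names(first_order_scores)
  fits
}

#' Winsorize values beyond k standard deviations from the mean
#'
#' Boundaries use the mean and SD computed before any modification.
#'
#' @param values numeric vector (length >= 2, non-zero SD).
#' @param k boundary in SD units (default 3).
#' @return list with \code{values} (winsorized) and \code{n_modified}.
#' @export
winsorize <- function(values, k = 3) {
  if (length(values) < 2) stop("need at least 2 values")
  mu <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("zero standard deviation")
  lo <- mu - k * s; hi <- mu + k * s
  out <- pmin(pmax(values, lo), hi)
  list(values = out, n_modified = sum(out != values, na.rm = TRUE))
}
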