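# Maximum-likelihood confirmatory factor analysis for the substance-use
# liability factor: three first-order factors (tobacco, cannabis, alcohol)
# and a single second-order liability factor. The fitted second-order
# factor score is the outcome of every downstream epigenome-wide analysis.
#
# Estimation minimizes the ML discrepancy
#   F_ML = log|Sigma(theta)| + tr(S Sigma^-1) - log|S| - p
# over free parameters; chi^2 = (N-1) F_ML at the optimum. Identification
# fixes the first loading of each factor (and of the second-order factor)
# to 1; variances are optimized on the log scale, which keeps solutions
# admissible by construction (a residual variance collapsing toward zero is
# reported as a Heywood-boundary flag rather than a negative estimate).

#' Default measurement model for adolescent substance use
#'
#' Three first-order factors over eight indicators (tobacco and cannabis at
#' 14/16/18, alcohol at 16/18), one second-order factor over the three.
#'
#' @return list with element \code{factors}: named list mapping each
#'   first-order factor to its indicator column names.
#' @export
liability_model_spec <- function() {
  list(factors = list(
    tobacco = c("tobacco_14", "tobacco_16", "tobacco_18"),
    cannabis = c("cannabis_14", "cannabis_16", "cannabis_18"),
    alcohol = c("alcohol_16", "alcohol_18")
  ))
}

# Expand a model spec into index structures.
.cfa_layout <- function(spec, item_names) {
  factors <- spec$factors
  items <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(items))
    stop("each indicator must map to exactly one first-order factor")
  if (!all(items %in% item_names))
    stop("indicators missing from data: ",
         paste(setdiff(items, item_names), collapse = ", "))
  p <- length(items)
  nf <- length(factors)
  item_fac <- rep(seq_len(nf), times = lengths(factors))
  marker <- match(vapply(factors, `[`, "", 1), items)
  free_load <- setdiff(seq_len(p), marker)
  npar <- length(free_load) + (nf - 1) + 1 + nf + p
  df <- p * (p + 1) / 2 - npar
  if (df <= 0) stop("model not identified (df <= 0)")
  list(items = items, p = p, nf = nf, item_fac = item_fac,
       marker = marker, free_load = free_load, npar = npar, df = df)
}

# Unpack parameter vector into model matrices.
.cfa_unpack <- function(par, ly) {
  p <- ly$p; nf <- ly$nf
  Lambda <- matrix(0, p, nf)
  Lambda[cbind(ly$marker, seq_len(nf))] <- 1
  k <- length(ly$free_load)
  Lambda[cbind(ly$free_load, ly$item_fac[ly$free_load])] <- par[seq_len(k)]
  Gamma <- c(1, par[k + seq_len(nf - 1)])
  i <- k + nf - 1
  phi <- exp(par[i + 1])
  Psi <- exp(par[i + 1 + seq_len(nf)])
  Theta <- exp(par[i + 1 + nf + seq_len(p)])
  list(Lambda = Lambda, Gamma = Gamma, phi = phi, Psi = Psi, Theta = Theta)
}

.cfa_sigma <- function(m) {
  Phi_F <- tcrossprod(m$Gamma) * m$phi + diag(m$Psi, length(m$Psi))
  m$Lambda %*% Phi_F %*% t(m$Lambda) + diag(m$Theta, nrow(m$Lambda))
}

.fml <- function(Sigma, S, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  val <- logdet + tr - logdetS - nrow(S)
  if (!is.finite(val)) 1e10 else val
}

#' Fit the first/second-order liability CFA by maximum likelihood
#'
#' @param data data.frame or matrix containing the indicator columns named
#'   in \code{spec}; rows with missing indicators are dropped
#'   (complete-case). Alternatively supply \code{sample_cov} and
#'   \code{n_obs} to fit from moments only.
#' @param spec model specification, see \code{\link{liability_model_spec}}.
#' @param sample_cov optional p x p covariance matrix (used when
#'   \code{data} is NULL); dimnames must name the indicators.
#' @param n_obs number of observations behind \code{sample_cov}.
#' @param scores whether to compute per-sample factor scores (needs raw
#'   data).
#' @return object of class \code{cfa_fit}: parameter estimates
#'   (unstandardized and standardized loadings), fit statistics
#'   (\code{chi_square}, \code{df}, \code{p_chi}, \code{CFI}, \code{TLI},
#'   \code{RMSEA} with 90\% CI), convergence and admissibility flags, and
#'   (when requested) factor scores for the second-order liability and the
#'   three first-order factors.
#' @export
fit_cfa <- function(data = NULL, spec = liability_model_spec(),
                    sample_cov = NULL, n_obs = NULL, scores = !is.null(data)) {
  if (is.null(data) && is.null(sample_cov))
    stop("supply either raw data or a sample covariance matrix")
  if (!is.null(data)) {
    ly <- .cfa_layout(spec, colnames(data))
    X <- as.matrix(as.data.frame(data)[, ly$items, drop = FALSE])
    X <- X[stats::complete.cases(X), , drop = FALSE]
    N <- nrow(X)
    S <- stats::cov(X)
  } else {
    ly <- .cfa_layout(spec, colnames(sample_cov))
    S <- sample_cov[ly$items, ly$items]
    N <- n_obs
    X <- NULL
  }
  if (is.null(N) || N <= ly$npar)
    stop("need more observations than free parameters")
  ch_S <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch_S)) stop("sample covariance is singular")
  logdetS <- 2 * sum(log(diag(ch_S)))

  par0 <- .cfa_start(S, ly)
  obj <- function(par) .fml(.cfa_sigma(.cfa_unpack(par, ly)), S, logdetS)
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-12))
  ## polish: restart once from the optimum (numeric-gradient BFGS can stall)
  opt2 <- stats::optim(opt$par, obj, method = "BFGS",
                       control = list(maxit = 5000, reltol = 1e-12))
  if (opt2$value < opt$value) opt <- opt2
  converged <- opt$convergence == 0
  est <- .cfa_unpack(opt$par, ly)
  est$mu <- if (!is.null(X)) colMeans(X) else rep(0, ly$p)
  Sigma <- .cfa_sigma(est)

  fml <- max(opt$value, 0)
  chi <- (N - 1) * fml
  df <- ly$df
  p_chi <- stats::pchisq(chi, df, lower.tail = FALSE)

  ## baseline (independence) model: free variances only
  chi0 <- -(N - 1) * determinant(stats::cov2cor(S), logarithm = TRUE)$modulus[1]
  df0 <- ly$p * (ly$p - 1) / 2
  CFI <- {
    num <- max(chi - df, 0)
    den <- max(chi0 - df0, chi - df, 0)
    if (den <= 0) 1 else 1 - num / den
  }
  TLI <- {
    r0 <- chi0 / df0; rm_ <- chi / df
    if (abs(r0 - 1) < .Machine$double.eps) 1 else (r0 - rm_) / (r0 - 1)
  }
  RMSEA <- sqrt(max(chi - df, 0) / (df * (N - 1)))
  ci <- rmsea_ci(chi, df, N)

  std <- .cfa_standardize(est, Sigma, ly)
  if (!is.null(names(spec$factors))) {
    fn <- names(spec$factors)
    std$loadings$factor <- fn[as.integer(sub("^F", "", std$loadings$factor))]
    std$second_order$factor <- fn
  }
  heywood <- any(est$Theta < 1e-6) || any(est$Psi < 1e-6)

  fit <- list(
    spec = spec, layout = ly, est = est, Sigma = Sigma, S = S, N = N,
    loadings = std$loadings, second_order = std$second_order,
    residual_variances = stats::setNames(est$Theta, ly$items),
    chi_square = chi, df = df, p_chi = p_chi,
    CFI = CFI, TLI = TLI, RMSEA = RMSEA, RMSEA_CI90 = ci,
    baseline = c(chi_square = chi0, df = df0),
    F_ML = fml, converged = converged, admissible = !heywood
  )
  class(fit) <- "cfa_fit"
  if (scores && !is.null(X)) fit$scores <- factor_scores(fit, X)
  fit
}

# Moment-based starting values: marker loadings are fixed at 1, so the
# within-factor covariances of the marker approximate the factor variance.
.cfa_start <- function(S, ly) {
  v <- numeric(ly$nf)
  for (s in seq_len(ly$nf)) {
    idx <- which(ly$item_fac == s)
    v[s] <- if (length(idx) > 1) {
      mean(S[ly$marker[s], setdiff(idx, ly$marker[s])])
    } else 0.5 * S[ly$marker[s], ly$marker[s]]
    v[s] <- max(v[s], 0.1 * S[ly$marker[s], ly$marker[s]])
  }
  phi0 <- max(stats::median(S[ly$marker, ly$marker][upper.tri(diag(ly$nf))]),
              0.05 * mean(diag(S)))
  psi0 <- pmax(v - phi0, 0.1 * v)
  load0 <- vapply(ly$free_load, function(i)
    S[i, ly$marker[ly$item_fac[i]]] / v[ly$item_fac[i]], 0)
  lam <- numeric(ly$p)
  lam[ly$marker] <- 1
  lam[ly$free_load] <- load0
  theta0 <- pmax(diag(S) - v[ly$item_fac] * lam^2, 0.1 * diag(S))
  c(load0, rep(1, ly$nf - 1), log(phi0), log(psi0), log(theta0))
}

# Standardized solution from the implied covariance.
.cfa_standardize <- function(est, Sigma, ly) {
  Phi_F <- tcrossprod(est$Gamma) * est$phi + diag(est$Psi, ly$nf)
  sdF <- sqrt(diag(Phi_F))
  sdY <- sqrt(diag(Sigma))
  raw <- est$Lambda[cbind(seq_len(ly$p), ly$item_fac)]
  fac_names <- paste0("F", seq_len(ly$nf))
  loadings <- data.frame(
    indicator = ly$items,
    factor = fac_names[ly$item_fac],
    unstd = raw,
    std = raw * sdF[ly$item_fac] / sdY,
    stringsAsFactors = FALSE
  )
  second <- data.frame(
    factor = fac_names,
    unstd = est$Gamma,
    std = est$Gamma * sqrt(est$phi) / sdF,
    stringsAsFactors = FALSE
  )
  list(loadings = loadings, second_order = second)
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf(
    "ML CFA: chi2(%d) = %.2f, p = %.3g, CFI = %.3f, TLI = %.3f, RMSEA = %.3f (90%% CI %.3f-%.3f)\n",
    x$df, x$chi_square, x$p_chi, x$CFI, x$TLI, x$RMSEA,
    x$RMSEA_CI90[1], x$RMSEA_CI90[2]))
  cat(sprintf("converged: %s; admissible: %s\n", x$converged, x$admissible))
  invisible(x)
}

#' Noncentrality-based confidence interval for the RMSEA
#'
#' Bounds invert the noncentral chi-square CDF: the lower (upper)
#' noncentrality solves \code{P(chisq_df(ncp) <= chi_square)} equal to
#' \code{1 - (1-level)/2} (resp. \code{(1-level)/2}); bounds are
#' \code{sqrt(ncp / (df (N-1)))} with noncentralities clipped at zero.
#'
#' @param chi_square observed model chi-square (>= 0).
#' @param df model degrees of freedom (>= 1).
#' @param N sample size (>= 2).
#' @param level confidence level; \code{level = 0} collapses both bounds to
#'   the median-based point value.
#' @return numeric vector \code{c(lower, upper)}.
#' @export
rmsea_ci <- function(chi_square, df, N, level = 0.90) {
  stopifnot(chi_square >= 0, df >= 1, N >= 2, level >= 0, level < 1)
  p_lo <- 1 - (1 - level) / 2
  p_hi <- (1 - level) / 2
  solve_ncp <- function(target) {
    f <- function(l) stats::pchisq(chi_square, df, ncp = l) - target
    if (f(0) < 0) return(0)  # even ncp=0 puts too little mass below chi2
    hi <- max(4 * chi_square, 4 * df, 1)
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
    if (f(hi) > 0) return(hi)
    stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  }
  lo <- sqrt(max(solve_ncp(p_lo), 0) / (df * (N - 1)))
  hi <- sqrt(max(solve_ncp(p_hi), 0) / (df * (N - 1)))
  c(lower = lo, upper = hi)
}

#' Regression-method factor scores
#'
#' Linear-in-data scores for the three first-order factors and the
#' second-order liability, using the fitted model's implied covariances:
#' \code{scores = Cov(factors, y) Sigma^-1 (y - mean)}. The second-order
#' score is standardized to mean 0, SD 1. A pseudo-inverse is used when the
#' implied covariance is singular (e.g. all unique variances zero).
#'
#' @param fit a \code{cfa_fit} (or any list carrying \code{est} and
#'   \code{layout} in the same shape).
#' @param data matrix/data.frame with the indicator columns.
#' @param method only \code{"regression"} is implemented.
#' @return data.frame with columns \code{liability} (standardized
#'   second-order score) and one column per first-order factor.
#' @export
factor_scores <- function(fit, data, method = "regression") {
  method <- match.arg(method, "regression")
  if (!is.null(fit$converged) && !fit$converged)
    stop("factor scores require a converged fit")
  ly <- fit$layout
  est <- fit$est
  X <- as.matrix(as.data.frame(data)[, ly$items, drop = FALSE])
  Phi_F <- tcrossprod(est$Gamma) * est$phi + diag(est$Psi, ly$nf)
  Sigma <- .cfa_sigma(est)
  cov_F_y <- Phi_F %*% t(est$Lambda)              # first-order factors vs y
  cov_xi_y <- est$phi * t(est$Gamma) %*% t(est$Lambda)  # liability vs y
  W <- rbind(cov_xi_y, cov_F_y) %*% pinv(Sigma)
  ctr <- sweep(X, 2, est$mu %||% colMeans(X))
  sc <- ctr %*% t(W)
  liab <- sc[, 1]
  if (stats::sd(liab) > 0) liab <- (liab - mean(liab)) / stats::sd(liab)
  out <- data.frame(liability = liab, sc[, -1, drop = FALSE])
  names(out)[-1] <- names(fit$spec$factors) %||%
    paste0("F", seq_len(ly$nf))
  rownames(out) <- rownames(X)
  out
}
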