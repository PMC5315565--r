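# Cumulative weighted DNA-methylation risk score.
#
# The score follows the polygenic-risk-score recipe: each selected probe's
# raw beta value is multiplied by its discovery-EWAS standardized
# regression coefficient (the weight) and the products are summed per
# sample. Weights are frozen at construction; the score object carries its
# provenance (discovery threshold, variant) so downstream analyses cannot
# silently re-derive weights on the testing data.

#' Compute the cumulative weighted methylation risk score
#'
#' @param M \code{\link{methylome}} or beta matrix containing all score
#'   probes.
#' @param dmps a \code{dmp_set} (probe ids + discovery standardized betas
#'   used as weights).
#' @param standardize if TRUE, return the z-scored score (flagged in the
#'   result); the default reports the raw weighted sum.
#' @param variant label recorded on the result ("full" or
#'   "mqtl_excluded").
#' @return data.frame (sample_id, score), class \code{risk_score}, with
#'   attributes \code{weights}, \code{variant}, \code{standardized}.
#' @export
compute_mrs <- function(M, dmps, standardize = FALSE, variant = "full") {
  beta <- if (inherits(M, "methylome")) M$beta else M
  miss <- setdiff(dmps$probe_id, colnames(beta))
  if (length(miss) > 0)
    stop("score probes missing from matrix: ", paste(miss, collapse = ", "))
  w <- stats::setNames(dmps$std_beta, dmps$probe_id)
  score <- as.numeric(beta[, dmps$probe_id, drop = FALSE] %*% w)
  if (standardize && stats::sd(score) > 0)
    score <- (score - mean(score)) / stats::sd(score)
  out <- data.frame(sample_id = rownames(beta), score = score,
                    stringsAsFactors = FALSE)
  attr(out, "weights") <- w
  attr(out, "variant") <- variant
  attr(out, "standardized") <- standardize
  attr(out, "q_threshold") <- attr(dmps, "q_threshold")
  class(out) <- c("risk_score", "data.frame")
  out
}

#' Drop mQTL-associated probes from a DMP set
#'
#' Produces the genetically de-confounded score variant: probes listed in
#' the mQTL lookup table are removed, with the removed count split by
#' cis/trans recorded on the result.
#'
#' @param dmps a \code{dmp_set}.
#' @param mqtl_table data.frame with columns \code{probe_id} and
#'   \code{type} ("cis"/"trans").
#' @return the reduced \code{dmp_set}; attributes \code{n_removed},
#'   \code{n_cis}, \code{n_trans}.
#' @export
exclude_mqtl_probes <- function(dmps, mqtl_table) {
  hit <- dmps$probe_id %in% mqtl_table$probe_id
  removed <- dmps$probe_id[hit]
  types <- mqtl_table$type[match(removed, mqtl_table$probe_id)]
  out <- dmps[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "q_threshold") <- attr(dmps, "q_threshold")
  attr(out, "m_total") <- attr(dmps, "m_total")
  attr(out, "n_removed") <- sum(hit)
  attr(out, "n_cis") <- sum(types == "cis")
  attr(out, "n_trans") <- sum(types == "trans")
  class(out) <- c("dmp_set", "data.frame")
  out
}

#' Screen prenatal exposures against the risk score and the outcome
#'
#' Pearson bivariate correlations of the methylation risk score (row 1)
#' and the substance-use outcome (row 2) with each exposure, with
#' Benjamini-Hochberg q-values computed within each row's exposure family.
#'
#' @param score numeric vector or \code{risk_score}.
#' @param outcome numeric vector (substance-use factor score).
#' @param exposures data.frame of exposure columns.
#' @return long-format data.frame: variable ("dnam_risk"/"substance_use"),
#'   exposure, n, r, p, q.
#' @export
screen_exposures <- function(score, outcome, exposures) {
  s <- if (inherits(score, "risk_score")) score$score else score
  exposures <- as.data.frame(exposures)
  rows <- list(dnam_risk = s, substance_use = outcome)
  out <- do.call(rbind, lapply(names(rows), function(v) {
    y <- rows[[v]]
    res <- do.call(rbind, lapply(names(exposures), function(e) {
      x <- exposures[[e]]
      ok <- stats::complete.cases(x, y)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        stop("constant column in screen: ", e)
      r <- stats::cor(x[ok], y[ok])
      data.frame(variable = v, exposure = e, n = sum(ok), r = r,
                 p = cor_pval(r, sum(ok)), stringsAsFactors = FALSE)
    }))
    res$q <- bh_adjust(res$p)
    res
  }))
  rownames(out) <- NULL
  out
}

#' Risk-score correlations with age of substance-use onset
#'
#' Pearson correlation of the score with onset age, computed within each
#' substance's endorsement subgroup only (onset is defined only for
#' endorsers).
#'
#' @param score numeric vector or \code{risk_score}.
#' @param onset data.frame of onset-age columns (NA for non-endorsers).
#' @param endorsed optional data.frame of logical endorsement columns,
#'   matched to \code{onset} columns by order; defaults to
#'   \code{!is.na(onset)}.
#' @return data.frame: substance, n (endorsers used), r, p; subgroups with
#'   fewer than 3 endorsers or constant onset are flagged and carry NA.
#' @export
onset_correlation <- function(score, onset, endorsed = NULL) {
  s <- if (inherits(score, "risk_score")) score$score else score
  onset <- as.data.frame(onset)
  out <- do.call(rbind, lapply(names(onset), function(cn) {
    age <- onset[[cn]]
    mask <- if (!is.null(endorsed)) endorsed[[match(cn, names(onset))]] else
      !is.na(age)
    ok <- mask & !is.na(age) & !is.na(s)
    n <- sum(ok)
    if (n < 3)
      return(data.frame(substance = cn, n = n, r = NA_real_, p = NA_real_,
                        flag = "too_few_endorsers", stringsAsFactors = FALSE))
    if (stats::sd(age[ok]) == 0)
      return(data.frame(substance = cn, n = n, r = NA_real_, p = NA_real_,
                        flag = "constant_onset", stringsAsFactors = FALSE))
    r <- stats::cor(s[ok], age[ok])
    data.frame(substance = cn, n = n, r = r, p = cor_pval(r, n), flag = "",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
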