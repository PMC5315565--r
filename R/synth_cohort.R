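# Synthetic two-timepoint methylation cohort generator.
#
# The generator emulates the design of a prospective neonatal-methylation /
# adolescent-substance-use study: Illumina-450k-style beta matrices at two
# timepoints (cord blood at birth, whole blood at mid-childhood), a
# second-order latent liability over 8 substance-use indicators, Dirichlet
# cell-type mixtures projected through a reference panel, mQTL genotype
# effects, prenatal-exposure effects, low genome-wide cross-time
# autocorrelation and a preserved within-time co-methylation block among the
# planted differentially methylated probes (DMPs). All effects are applied on
# the logit(beta) scale so that inverse transformation keeps betas in (0,1).

#' Configuration for the synthetic cohort generator
#'
#' Returns a validated configuration list. Defaults are calibrated to the
#' study design the generator emulates: two timepoints, five blood cell
#' types, 65 planted DMPs of which 5 are under mQTL control, standardized
#' indicator loadings in the 0.58-0.96 range, and weak genome-wide
#' cross-time autocorrelation (mean per-probe r around 0.07).
#'
#' @param n_samples number of individuals (default 500, desk scale).
#' @param n_probes number of CpG probes (default 20000, desk scale).
#' @param n_dmps number of probes with planted liability effects.
#' @param n_mqtl_dmps number of the planted DMPs additionally under genetic
#'   (mQTL) control; must not exceed \code{n_dmps}.
#' @param dmp_effect_sd magnitude of the planted liability effect on the
#'   logit-beta scale per unit latent liability. The default 0.12, together
#'   with \code{noise_sd}, yields probe-level standardized effects around
#'   0.3, the magnitude reported for replicated neonatal DMPs.
#' @param exposure_effects named list, one entry per exposure, each a list
#'   with elements \code{n} (affected probes) and \code{effect} (logit-scale
#'   shift per unit exposure). These probes are distinct from the liability
#'   DMPs (they emulate e.g. the AHRR-type prenatal-smoking signature).
#' @param liability_exposure_coefs named numeric vector: standardized path
#'   from each exposure to the latent liability. The default places the only
#'   nonzero path on maternal smoking, so mediation
#'   (exposure -> methylation -> substance use) holds by construction.
#' @param mqtl_effect logit-beta shift per minor allele at mQTL probes.
#' @param mqtl_maf minor allele frequency for Hardy-Weinberg genotypes.
#' @param cross_time_autocorr target per-probe Pearson r between timepoints
#'   for non-mQTL probes.
#' @param comethylation_block_corr exchangeable residual correlation among
#'   the planted DMPs within each timepoint.
#' @param factor_loadings list with \code{first_order} (8 standardized
#'   loadings: tobacco 14/16/18, cannabis 14/16/18, alcohol 16/18) and
#'   \code{second_order} (3 loadings of the substance factors on the general
#'   liability).
#' @param cell_types character vector of reference cell-type labels.
#' @param dirichlet_alpha Dirichlet concentration vector, one per cell type.
#' @param cell_effect_sd logit-scale SD of cell-type effects on non-panel
#'   probes.
#' @param n_panel_probes probes carried by the reference panel.
#' @param noise_sd logit-scale residual SD.
#' @param sex_ratio_female probability a sample is female.
#' @param smoking_prevalence probability of prenatal maternal smoking.
#' @param onset_endorse_rates endorsement probabilities for the three
#'   age-of-onset items (cigarette, cannabis, alcohol).
#' @param onset_liability_r target correlation between latent liability and
#'   (negative) age of onset among endorsers.
#' @param n_flagged integer vector of length 3: probes to flag as
#'   cross-reactive, control, and SNP-at-single-base-extension (MAF > 5%)
#'   respectively; flagged probes are removed by \code{\link{filter_probes}}.
#' @param seed integer seed; fully determines all outputs.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 500,
                       n_probes = 20000,
                       n_dmps = 65,
                       n_mqtl_dmps = 5,
                       dmp_effect_sd = 0.12,
                       exposure_effects = list(
                         maternal_smoking = list(n = 20, effect = 0.5)
                       ),
                       liability_exposure_coefs = c(maternal_smoking = 0.3),
                       mqtl_effect = 0.8,
                       mqtl_maf = 0.3,
                       cross_time_autocorr = 0.07,
                       comethylation_block_corr = 0.3,
                       factor_loadings = list(
                         first_order = c(0.75, 0.85, 0.80,
                                         0.70, 0.90, 0.85,
                                         0.65, 0.80),
                         second_order = c(0.85, 0.80, 0.75)
                       ),
                       cell_types = c("CD8T", "CD4T", "NK", "Bcell", "Mono"),
                       dirichlet_alpha = c(8, 16, 4, 6, 10),
                       cell_effect_sd = 0.15,
                       n_panel_probes = 200,
                       noise_sd = 0.35,
                       sex_ratio_female = 0.51,
                       smoking_prevalence = 0.18,
                       onset_endorse_rates = c(cigarette = 0.53,
                                               cannabis = 0.38,
                                               alcohol = 0.80),
                       onset_liability_r = -0.3,
                       n_flagged = c(cross_reactive = 0L,
                                     control_probe = 0L,
                                     snp_at_sbe = 0L),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_samples >= 2, n_probes >= 1,
    n_dmps >= 0, n_dmps <= n_probes,
    n_mqtl_dmps >= 0, n_mqtl_dmps <= n_dmps,
    dmp_effect_sd >= 0, mqtl_maf > 0, mqtl_maf < 1,
    abs(cross_time_autocorr) < 1,
    comethylation_block_corr >= 0, comethylation_block_corr < 1,
    length(factor_loadings$first_order) == 8,
    length(factor_loadings$second_order) == 3,
    all(is.finite(factor_loadings$first_order)),
    all(is.finite(factor_loadings$second_order)),
    all(abs(factor_loadings$first_order) <= 1),
    all(abs(factor_loadings$second_order) <= 1),
    length(cell_types) >= 2,
    length(dirichlet_alpha) == length(cell_types),
    all(dirichlet_alpha > 0),
    noise_sd > 0, sex_ratio_female > 0, sex_ratio_female < 1,
    length(n_flagged) == 3, sum(n_flagged) <= n_probes,
    length(seed) == 1, is.finite(seed)
  )
  if (any(abs(liability_exposure_coefs) >= 1))
    stop("liability_exposure_coefs must be standardized paths in (-1, 1)")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Methylome matrix container
#'
#' Bundles a samples x probes beta matrix with its probe annotation
#' (chromosome, 1-based position, gene label, QC flags) and a timepoint
#' label. Betas must lie strictly inside (0,1) with no missing values.
#'
#' @param beta numeric matrix, samples in rows, probes in columns; dimnames
#'   required.
#' @param annotation data.frame with columns \code{probe_id}, \code{chrom},
#'   \code{pos}, \code{gene}, \code{cross_reactive}, \code{control_probe},
#'   \code{snp_at_sbe}; one row per probe, same order as \code{beta} columns.
#' @param timepoint character label (e.g. "birth", "age7").
#' @return object of class \code{methylome}.
#' @export
methylome <- function(beta, annotation, timepoint = "birth") {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  if (anyNA(beta)) stop("beta matrix contains missing values")
  if (any(beta <= 0 | beta >= 1)) stop("beta values must lie strictly in (0,1)")
  need <- c("probe_id", "chrom", "pos", "gene",
            "cross_reactive", "control_probe", "snp_at_sbe")
  if (!all(need %in% names(annotation)))
    stop("annotation missing columns: ",
         paste(setdiff(need, names(annotation)), collapse = ", "))
  if (!identical(as.character(annotation$probe_id), colnames(beta)))
    stop("annotation rows must match beta columns (same probes, same order)")
  if (anyDuplicated(annotation$probe_id)) stop("duplicate probe ids")
  if (any(annotation$pos < 0) || any(annotation$pos != floor(annotation$pos)))
    stop("positions must be non-negative integers")
  structure(list(beta = beta, annotation = annotation, timepoint = timepoint),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> %d samples x %d probes, timepoint = %s\n",
              nrow(x$beta), ncol(x$beta), x$timepoint))
  invisible(x)
}

# Dirichlet draws via normalized gammas.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate substance-use indicators from a two-level factor model
#'
#' Eight indicators (tobacco and cannabis at ages 14/16/18, alcohol at
#' 16/18) load on three first-order substance factors, which in turn load on
#' the general liability \code{L}. Loadings are standardized: each
#' first-order factor is \code{g*L + sqrt(1-g^2)*disturbance} and each
#' indicator \code{l*F + sqrt(1-l^2)*error}, so all variables have unit
#' variance when \code{L} does.
#'
#' @param L numeric vector of latent liability values (one per sample).
#' @param loadings list with \code{first_order} (length 8) and
#'   \code{second_order} (length 3); see \code{\link{sim_config}}.
#' @param seed optional integer; when supplied the RNG state is set locally.
#' @return list with \code{items} (n x 8 matrix) and \code{first_order}
#'   (n x 3 matrix of true first-order factor scores).
#' @export
simulate_substance_items <- function(L, loadings, seed = NULL) {
  if (length(loadings$first_order) != 8 || length(loadings$second_order) != 3)
    stop("expected 8 first-order and 3 second-order loadings")
  if (!is.null(seed)) set.seed(seed)
  n <- length(L)
  g <- loadings$second_order
  l <- loadings$first_order
  fac_names <- c("tobacco", "cannabis", "alcohol")
  item_fac <- c(1, 1, 1, 2, 2, 2, 3, 3)
  item_names <- c("tobacco_14", "tobacco_16", "tobacco_18",
                  "cannabis_14", "cannabis_16", "cannabis_18",
                  "alcohol_16", "alcohol_18")
  Fmat <- sapply(1:3, function(s)
    g[s] * L + sqrt(1 - g[s]^2) * stats::rnorm(n))
  colnames(Fmat) <- fac_names
  items <- sapply(1:8, function(i)
    l[i] * Fmat[, item_fac[i]] + sqrt(1 - l[i]^2) * stats::rnorm(n))
  colnames(items) <- item_names
  list(items = items, first_order = Fmat)
}

#' Simulate a full two-timepoint methylation cohort with planted truth
#'
#' Generates, from a single seed, everything the analysis pipeline consumes:
#' beta matrices at birth and mid-childhood, a phenotype table, a cell-type
#' reference panel, an mQTL lookup table, and the ground truth needed for
#' parameter-recovery tests.
#'
#' The probe-level model on the logit(beta) scale at birth is
#' \code{mu_j + lambda_j*L_i + sum_e gamma_ej*E_ie + delta_j*G_ij +
#' sum_k c_kj*pi_ik + eps_ij} with Gaussian residuals; residuals across the
#' planted DMPs share an exchangeable correlation block. The second
#' timepoint keeps the probe baseline and genotype terms, carries no
#' liability or exposure effects (effects are specific to birth), regenerates
#' the cell and residual components with a fresh co-methylation block, and
#' mixes in the birth component so non-mQTL probes attain the configured
#' cross-time autocorrelation while mQTL probes stay stable through their
#' shared genotype term.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{birth} and \code{age7} (methylome
#'   objects), \code{cohort} (phenotype data.frame), \code{truth} (ground
#'   truth list), \code{panel} (reference panel data.frame), and
#'   \code{mqtl_table}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_probes
  K <- length(config$cell_types)

  sample_ids <- sprintf("S%04d", seq_len(n))
  probe_ids <- sprintf("cg%08d", seq_len(p))

  ## --- annotation: contiguous chromosome blocks, increasing positions ---
  n_chr <- min(22L, p)
  chrom_of <- sort(rep_len(seq_len(n_chr), p))
  gaps <- sample(50:5000, p, replace = TRUE)
  pos <- integer(p)
  for (ch in seq_len(n_chr)) {
    idx <- which(chrom_of == ch)
    pos[idx] <- 10000L + cumsum(gaps[idx])
  }
  flags <- matrix(FALSE, p, 3,
                  dimnames = list(NULL, c("cross_reactive", "control_probe",
                                          "snp_at_sbe")))
  if (sum(config$n_flagged) > 0) {
    flag_idx <- sample.int(p, sum(config$n_flagged))
    splits <- rep(1:3, times = config$n_flagged)
    for (j in 1:3) flags[flag_idx[splits == j], j] <- TRUE
  }
  annotation <- data.frame(
    probe_id = probe_ids,
    chrom = paste0("chr", chrom_of),
    pos = pos,
    gene = ifelse(seq_len(p) %% 3 == 0, "",
                  sprintf("GENE%05d", (seq_len(p) - 1) %/% 5 + 1)),
    cross_reactive = flags[, 1],
    control_probe = flags[, 2],
    snp_at_sbe = flags[, 3],
    stringsAsFactors = FALSE
  )

  ## --- phenotypes and exposures ---
  sex <- stats::rbinom(n, 1, config$sex_ratio_female)  # 1 = female
  maternal_smoking <- stats::rbinom(n, 1, config$smoking_prevalence)
  maternal_alcohol <- sample(0:3, n, replace = TRUE,
                             prob = c(0.35, 0.35, 0.2, 0.1))
  cont_exp <- matrix(stats::rnorm(n * 4), n, 4,
                     dimnames = list(NULL, c("life_events", "contextual_risks",
                                             "parental_risks",
                                             "interpersonal_risks")))
  exposures <- cbind(
    maternal_smoking = maternal_smoking,
    maternal_alcohol = maternal_alcohol,
    cont_exp
  )

  ## --- latent liability: partially determined by exposures ---
  coefs <- config$liability_exposure_coefs
  L <- stats::rnorm(n) * sqrt(max(0, 1 - sum(coefs^2)))
  for (e in names(coefs)) {
    x <- exposures[, e]
    xs <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    L <- L + coefs[[e]] * xs
  }

  ## --- substance-use indicators and onset items ---
  su <- simulate_substance_items(L, config$factor_loadings)
  onset <- .simulate_onset(L, su$first_order, config)

  cohort <- data.frame(sample_id = sample_ids, sex = sex,
                       exposures, su$items, onset,
                       stringsAsFactors = FALSE)

  ## --- probe roles: panel, DMPs, exposure probes, mQTL subset ---
  pool <- seq_len(p)
  panel_idx <- sort(sample(pool, min(config$n_panel_probes, p)))
  pool <- setdiff(pool, panel_idx)
  dmp_idx <- sort(sample(pool, config$n_dmps))
  pool <- setdiff(pool, dmp_idx)
  exposure_probes <- list()
  for (e in names(config$exposure_effects)) {
    ne <- config$exposure_effects[[e]]$n
    idx <- sort(sample(pool, min(ne, length(pool))))
    pool <- setdiff(pool, idx)
    exposure_probes[[e]] <- idx
  }
  mqtl_idx <- if (config$n_mqtl_dmps > 0)
    sort(sample(dmp_idx, config$n_mqtl_dmps)) else integer(0)

  ## --- probe-level parameters ---
  mu <- stats::rnorm(p, 0, 1.2)
  lambda <- numeric(p)
  if (config$n_dmps > 0) {
    signs <- rep_len(c(-1, 1), config$n_dmps)[sample.int(config$n_dmps)]
    lambda[dmp_idx] <- signs * config$dmp_effect_sd
  }
  gamma <- matrix(0, p, length(exposure_probes),
                  dimnames = list(NULL, names(exposure_probes)))
  for (e in names(exposure_probes)) {
    ne <- length(exposure_probes[[e]])
    gamma[exposure_probes[[e]], e] <-
      rep_len(c(-1, 1), ne)[sample.int(ne)] * config$exposure_effects[[e]]$effect
  }
  delta <- numeric(p)
  delta[mqtl_idx] <- config$mqtl_effect
  genotypes <- matrix(stats::rbinom(n * length(mqtl_idx), 2, config$mqtl_maf),
                      n, length(mqtl_idx),
                      dimnames = list(sample_ids, probe_ids[mqtl_idx]))

  ## cell-type logit signatures: strong contrasts on panel probes, mild
  ## loadings elsewhere
  cell_sig <- matrix(stats::rnorm(p * K, 0, config$cell_effect_sd), p, K)
  cell_sig[panel_idx, ] <- stats::rnorm(length(panel_idx) * K, 0, 1.5)
  pi1 <- rdirichlet(n, config$dirichlet_alpha)
  pi2 <- rdirichlet(n, config$dirichlet_alpha)
  colnames(pi1) <- colnames(pi2) <- config$cell_types
  rownames(pi1) <- rownames(pi2) <- sample_ids

  ## --- birth timepoint: birth-specific effects + persistent background ---
  ## only the background (cell + residual) component carries over to the
  ## second timepoint; liability and exposure effects are birth-specific,
  ## so the later timepoint carries zero planted effect by construction
  background1 <- .block_residuals(n, p, dmp_idx, config) +
    pi1 %*% t(cell_sig)
  b1 <- tcrossprod(L, lambda) + background1
  for (e in names(exposure_probes)) {
    x <- exposures[, e]
    xs <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    b1 <- b1 + tcrossprod(xs, gamma[, e])
  }

  fixed <- matrix(mu, n, p, byrow = TRUE)
  if (length(mqtl_idx) > 0)
    fixed[, mqtl_idx] <- fixed[, mqtl_idx] +
      genotypes * matrix(delta[mqtl_idx], n, length(mqtl_idx), byrow = TRUE)

  logit1 <- fixed + b1

  ## --- age-7 timepoint: fresh component with the same co-methylation
  ## block, mixed with the birth background at the target autocorrelation
  b2_ind <- .block_residuals(n, p, dmp_idx, config) + pi2 %*% t(cell_sig)
  rho <- config$cross_time_autocorr
  ## rescale the independent part per probe so t2 marginal spread matches
  s1 <- matrix(apply(background1, 2, stats::sd), n, p, byrow = TRUE)
  s2 <- matrix(apply(b2_ind, 2, stats::sd), n, p, byrow = TRUE)
  s2[s2 == 0] <- 1
  b2 <- rho * background1 + sqrt(1 - rho^2) * b2_ind * (s1 / s2)
  logit2 <- fixed + b2

  clamp <- function(x) pmin(pmax(inv_logit(x), 1e-6), 1 - 1e-6)
  beta1 <- clamp(logit1); beta2 <- clamp(logit2)
  dimnames(beta1) <- dimnames(beta2) <- list(sample_ids, probe_ids)

  panel <- data.frame(probe_id = probe_ids[panel_idx],
                      inv_logit(cell_sig[panel_idx, , drop = FALSE]),
                      stringsAsFactors = FALSE)
  names(panel) <- c("probe_id", config$cell_types)

  mqtl_table <- if (length(mqtl_idx) > 0) data.frame(
    probe_id = probe_ids[mqtl_idx],
    snp_id = sprintf("rs%07d", seq_along(mqtl_idx)),
    type = c(rep("cis", max(0, length(mqtl_idx) - 1)),
             rep("trans", min(1, length(mqtl_idx)))),
    stringsAsFactors = FALSE
  ) else data.frame(probe_id = character(0), snp_id = character(0),
                    type = character(0), stringsAsFactors = FALSE)

  truth <- list(
    dmp_ids = probe_ids[dmp_idx],
    dmp_effects = stats::setNames(lambda[dmp_idx], probe_ids[dmp_idx]),
    mqtl_probe_ids = probe_ids[mqtl_idx],
    mqtl_effects = stats::setNames(delta[mqtl_idx], probe_ids[mqtl_idx]),
    genotypes = genotypes,
    exposure_probe_ids = lapply(exposure_probes, function(i) probe_ids[i]),
    exposure_effects = lapply(names(exposure_probes), function(e)
      stats::setNames(gamma[exposure_probes[[e]], e],
                      probe_ids[exposure_probes[[e]]])),
    cell_proportions = list(birth = pi1, age7 = pi2),
    liability = stats::setNames(L, sample_ids),
    first_order_factors = su$first_order,
    factor_loadings = config$factor_loadings,
    config = config
  )
  names(truth$exposure_effects) <- names(exposure_probes)

  list(
    birth = methylome(beta1, annotation, "birth"),
    age7 = methylome(beta2, annotation, "age7"),
    cohort = cohort,
    truth = truth,
    panel = panel,
    mqtl_table = mqtl_table
  )
}

# Residual matrix with an exchangeable correlation block over the DMP probes
# (the planted co-methylation network); iid elsewhere.
.block_residuals <- function(n, p, dmp_idx, config) {
  eps <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
  rb <- config$comethylation_block_corr
  if (rb > 0 && length(dmp_idx) > 1) {
    shared <- stats::rnorm(n, 0, config$noise_sd)
    eps[, dmp_idx] <- sqrt(rb) * shared +
      sqrt(1 - rb) * eps[, dmp_idx, drop = FALSE]
  }
  eps
}

# Age-of-onset items: present only among endorsers, negatively related to
# liability with the configured target correlation.
.simulate_onset <- function(L, first_order, config) {
  n <- length(L)
  r <- config$onset_liability_r
  out <- data.frame(row.names = seq_len(n))
  subs <- c(cigarette = "tobacco", cannabis = "cannabis", alcohol = "alcohol")
  base_age <- c(cigarette = 15, cannabis = 15.5, alcohol = 14.5)
  for (s in names(subs)) {
    rate <- config$onset_endorse_rates[[s]]
    ## endorsement more likely at higher substance-specific factor values
    eta <- first_order[, subs[[s]]] + stats::qlogis(rate)
    endorse <- stats::rbinom(n, 1, stats::plogis(eta)) == 1
    age <- base_age[[s]] + r * L + sqrt(1 - r^2) * stats::rnorm(n)
    age[!endorse] <- NA_real_
    out[[paste0("endorsed_", s)]] <- endorse
    out[[paste0("onset_age_", s)]] <- round(age, 1)
  }
  out
}

#' Simulate a simple three-variable mediation dataset
#'
#' Generates (exposures, mediator, outcome) with known unstandardized paths
#' for testing the path-model machinery: \code{M = a*X1 + e_M},
#' \code{Y = b*M + cprime*X1 + e_Y}, all marginal variances 1. Additional
#' exposures are independent noise (null paths).
#'
#' @param n sample size.
#' @param a path from the focal exposure to the mediator.
#' @param b path from the mediator to the outcome.
#' @param cprime direct path from the focal exposure to the outcome.
#' @param n_null_exposures extra exposures with no effect.
#' @param seed integer seed.
#' @return list with \code{exposures} (matrix), \code{mediator},
#'   \code{outcome}, and the true \code{indirect} effect a*b.
#' @export
simulate_mediation_data <- function(n, a = 0.4, b = 0.5, cprime = 0.1,
                                    n_null_exposures = 2, seed = 1) {
  stopifnot(a^2 < 1)
  set.seed(seed)
  X1 <- stats::rnorm(n)
  M <- a * X1 + sqrt(1 - a^2) * stats::rnorm(n)
  vy <- b^2 + cprime^2 + 2 * a * b * cprime
  if (vy >= 1) stop("paths imply outcome variance above 1; shrink them")
  Y <- b * M + cprime * X1 + sqrt(1 - vy) * stats::rnorm(n)
  Xnull <- matrix(stats::rnorm(n * n_null_exposures), n, n_null_exposures)
  exposures <- cbind(X1, Xnull)
  colnames(exposures) <- c("exposure_1",
                           if (n_null_exposures > 0)
                             paste0("null_exposure_", seq_len(n_null_exposures)))
  list(exposures = exposures, mediator = M, outcome = Y, indirect = a * b)
}
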