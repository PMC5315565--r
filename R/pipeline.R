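# End-to-end orchestration: simulate (or load) -> probe QC -> liability CFA
# -> cell composition -> discovery EWAS at birth -> region calling ->
# follow-forward at the later timepoint -> autocorrelation and
# co-methylation -> risk scores (full and mQTL-excluded) -> exposure screen
# -> mediation. Stage artifacts are persisted as plain-text files and every
# number in the report is traceable to a stage output.

#' Pipeline configuration
#'
#' @param sim a \code{\link{sim_config}} describing the synthetic cohort to
#'   generate, or NULL when loading a written fixture via \code{input_dir}.
#' @param input_dir directory containing a fixture written by
#'   \code{\link{write_fixture}}; exactly one of \code{sim} /
#'   \code{input_dir} must be supplied.
#' @param q_dmp FDR threshold for discovery and replication (default 0.05).
#' @param dmr_seed_p seed p threshold for region calling (default 1e-4).
#' @param dmr_window window size in bp (default 500).
#' @param boot_B bootstrap replicate count for the mediation stage.
#' @param seed root seed for the pipeline's own randomness (bootstrap,
#'   permutations); the generator uses the seed inside \code{sim}.
#' @param outdir optional directory for stage artifacts; NULL keeps
#'   everything in memory.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            q_dmp = 0.05, dmr_seed_p = 1e-4,
                            dmr_window = 500, boot_B = 1000, seed = 1,
                            outdir = NULL) {
  if (is.null(sim) == is.null(input_dir))
    stop("supply exactly one of `sim` or `input_dir`")
  stopifnot(q_dmp > 0, q_dmp < 1, dmr_seed_p > 0, dmr_seed_p < 1,
            dmr_window > 0, boot_B >= 100)
  structure(list(sim = sim, input_dir = input_dir, q_dmp = q_dmp,
                 dmr_seed_p = dmr_seed_p, dmr_window = dmr_window,
                 boot_B = boot_B, seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{pipeline_config}};
#' a \code{sim:} block holds \code{\link{sim_config}} arguments.
#'
#' @param path YAML file path.
#' @return \code{pipeline_config}.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  args <- y[setdiff(names(y), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and returns a structured report. Stages
#' that cannot run (no DMPs discovered, or no exposure passing the screen)
#' are skipped gracefully with the reason recorded. Identical
#' configurations (including seeds) reproduce identical reports.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{pipeline_report}; see the methods vignette
#'   for the stage-by-stage contents.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(config = config,
              version = as.character(utils::packageVersion("methrisk")),
              seed = config$seed)

  data <- if (!is.null(config$sim)) simulate_cohort(config$sim)
          else read_fixture(config$input_dir)
  if (!is.null(config$outdir) && !is.null(config$sim))
    write_fixture(data, file.path(config$outdir, "cohort"))

  ## --- probe QC ---
  kept <- filter_probes(data$birth$annotation)
  out$qc <- list(n_probes_total = ncol(data$birth$beta),
                 n_probes_kept = length(kept))

  ## --- liability CFA and factor scores ---
  cfa <- fit_cfa(data$cohort, liability_model_spec())
  out$cfa <- list(chi_square = cfa$chi_square, df = cfa$df,
                  p_chi = cfa$p_chi, CFI = cfa$CFI, TLI = cfa$TLI,
                  RMSEA = cfa$RMSEA, RMSEA_CI90 = cfa$RMSEA_CI90,
                  converged = cfa$converged, admissible = cfa$admissible,
                  loadings = cfa$loadings, second_order = cfa$second_order)
  scores <- cfa$scores
  liability <- scores$liability

  ## --- cell composition (both timepoints) ---
  props1 <- estimate_proportions(data$birth, data$panel)
  props2 <- estimate_proportions(data$age7, data$panel)
  out$cells <- list(mean_proportions_birth = colMeans(props1))

  covar1 <- data.frame(sex = data$cohort$sex, props1)
  covar2 <- data.frame(sex = data$cohort$sex, props2)

  ## --- discovery EWAS at birth ---
  ewas1 <- run_ewas(data$birth, liability, covar1, probes = kept)
  dmps <- select_dmps(ewas1, config$q_dmp)
  out$ewas_birth <- list(
    n_tested = attr(ewas1, "m_total"),
    n_dmps = nrow(dmps),
    n_hypo = sum(dmps$std_beta < 0),
    n_hyper = sum(dmps$std_beta > 0),
    top = if (nrow(dmps) > 0) dmps[1, ] else NULL
  )

  ## --- region calling on the discovery p-value track ---
  ann <- data$birth$annotation
  keep_idx <- match(ewas1$probe_id[!is.na(ewas1$p)], ann$probe_id)
  track <- pval_track(ann$chrom[keep_idx], ann$pos[keep_idx],
                      ewas1$p[!is.na(ewas1$p)],
                      ann$probe_id[keep_idx])
  dmrs <- call_dmrs(track, p_threshold = config$dmr_seed_p,
                    window = config$dmr_window)
  out$dmr <- list(n_candidate = nrow(dmrs),
                  n_significant = sum(dmrs$p_sidak < 0.05))

  if (nrow(dmps) == 0) {
    out$skipped <- "no DMPs at the discovery threshold; downstream stages skipped"
    class(out) <- "pipeline_report"
    .write_report(out, config$outdir)
    return(out)
  }

  ## --- follow-forward, autocorrelation, co-methylation ---
  ff <- follow_forward(dmps, data$age7, liability, covar2, config$q_dmp)
  auto <- probe_autocorrelation(data$birth, data$age7, dmps$probe_id)
  out$follow_forward <- list(n_replicated = attr(ff, "n_replicated"),
                             n_nominal = length(attr(ff, "nominal")),
                             autocorrelation = auto$summary)
  if (nrow(dmps) >= 2) {
    cm1 <- comethylation_structure(data$birth, dmps$probe_id)
    cm2 <- comethylation_structure(data$age7, dmps$probe_id)
    cmp <- compare_structures(cm1$R, cm2$R, seed = config$seed)
    out$comethylation <- list(birth = cm1$summary, age7 = cm2$summary,
                              similarity = cmp$similarity,
                              mantel_p = cmp$mantel_p)
  }

  ## --- risk scores ---
  mrs_full <- compute_mrs(data$birth, dmps, variant = "full")
  dmps_red <- exclude_mqtl_probes(dmps, data$mqtl_table)
  out$mrs <- list(n_probes_full = nrow(dmps),
                  n_mqtl_removed = attr(dmps_red, "n_removed"),
                  n_cis = attr(dmps_red, "n_cis"),
                  n_trans = attr(dmps_red, "n_trans"))
  if (nrow(dmps_red) > 0) {
    mrs_red <- compute_mrs(data$birth, dmps_red, variant = "mqtl_excluded")
    out$mrs$cor_full_reduced <- stats::cor(mrs_full$score, mrs_red$score)
  }

  ## --- exposure screen ---
  exposure_cols <- c("maternal_smoking", "maternal_alcohol", "maternal_risks",
                     "family_risks", "contextual_risks", "life_events")
  ## generator names parental/interpersonal risks after their content; map
  ## to the conventional maternal/family labels for reporting
  expo <- data.frame(
    maternal_smoking = data$cohort$maternal_smoking,
    maternal_alcohol = data$cohort$maternal_alcohol,
    maternal_risks = data$cohort$parental_risks,
    family_risks = data$cohort$interpersonal_risks,
    contextual_risks = data$cohort$contextual_risks,
    life_events = data$cohort$life_events
  )
  screen <- screen_exposures(mrs_full, liability, expo)
  out$screen <- screen
  sig_exp <- screen$exposure[screen$variable == "dnam_risk" &
                               screen$q < 0.05]

  ## --- age-of-onset correlations ---
  onset_cols <- grep("^onset_age_", names(data$cohort), value = TRUE)
  if (length(onset_cols) > 0)
    out$onset <- onset_correlation(mrs_full, data$cohort[onset_cols])

  ## --- mediation ---
  if (length(sig_exp) == 0) {
    out$mediation <- list(skipped = "no exposure passed the q<0.05 screen")
  } else {
    med <- bootstrap_ci(expo[, sig_exp, drop = FALSE],
                        scale(mrs_full$score)[, 1], liability,
                        B = config$boot_B, seed = config$seed)
    out$mediation <- list(exposures = sig_exp, n = med$n, B = med$B,
                          indirect = med$indirect, ci = med$ci,
                          n_redrawn = med$n_redrawn)
  }

  class(out) <- "pipeline_report"
  .write_report(out, config$outdir)
  out
}

.write_report <- function(report, outdir) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  clean <- report
  clean$config$sim <- if (!is.null(clean$config$sim))
    unclass(clean$config$sim)
  clean$config <- unclass(clean$config)
  jsonlite::write_json(clean, file.path(outdir, "pipeline_report.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE,
                       pretty = TRUE)
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  probes kept after QC: %d / %d\n", x$qc$n_probes_kept,
              x$qc$n_probes_total))
  cat(sprintf("  CFA: chi2(%d) = %.2f, CFI = %.3f, RMSEA = %.3f\n",
              x$cfa$df, x$cfa$chi_square, x$cfa$CFI, x$cfa$RMSEA))
  cat(sprintf("  discovery DMPs (q < %.2g): %d (%d hypo / %d hyper)\n",
              x$config$q_dmp, x$ewas_birth$n_dmps, x$ewas_birth$n_hypo,
              x$ewas_birth$n_hyper))
  cat(sprintf("  significant DMRs: %d\n", x$dmr$n_significant))
  if (!is.null(x$follow_forward))
    cat(sprintf("  follow-forward replications: %d (nominal: %d)\n",
                x$follow_forward$n_replicated, x$follow_forward$n_nominal))
  if (!is.null(x$mediation$indirect)) {
    cat("  mediation indirect effects:\n")
    print(x$mediation$indirect[, c("exposure", "est", "se", "p")],
          row.names = FALSE)
  } else if (!is.null(x$mediation$skipped)) {
    cat("  mediation skipped:", x$mediation$skipped, "\n")
  }
  invisible(x)
}
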