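# Published worked-example inputs.

#' Published neonatal DMP summary statistics
#'
#' The printed per-probe summary statistics for the 65 cord-blood probes
#' reported to prospectively associate with adolescent substance use in the
#' motivating epidemiological cohort (ALSPAC subsample, Illumina 450k,
#' m = 413,510 probes after QC): probe id, annotated gene, chromosome,
#' genomic location class, position, standardized regression coefficient,
#' p-value and FDR q-value. Used as worked-example inputs — e.g. re-deriving
#' the printed top-probe q-value by Benjamini-Hochberg adjustment of the
#' printed p-values against the full test count, and as paper-scale weights
#' for risk-score arithmetic.
#'
#' @return data.frame with 65 rows.
#' @export
published_dmp_stats <- function() {
  path <- system.file("extdata", "published_dmp_stats_birth.tsv",
                      package = "methrisk", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Total post-QC probe count of the motivating study
#'
#' The number of probes retained after removing cross-reactive probes,
#' sample-identification probes and probes with a common polymorphism at
#' the single-base extension on the 450k array, in the motivating cohort.
#'
#' @return integer.
#' @export
published_m_total <- function() 413510L
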