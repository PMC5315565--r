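# Plain-text serialization of simulated cohorts.
#
# Formats: beta matrices as TSV with samples in rows (first column
# sample_id, remaining columns probe ids); annotation as a BED-like TSV;
# cohort table as CSV; reference panel and mQTL table as TSV; ground truth
# and generator configuration as JSON. Deterministic: the same cohort
# writes byte-identical files.

#' Write a simulated cohort to disk as plain-text files
#'
#' @param cohort list as returned by \code{\link{simulate_cohort}}.
#' @param outdir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    beta_birth = file.path(outdir, "beta_birth.tsv"),
    beta_age7 = file.path(outdir, "beta_age7.tsv"),
    annotation = file.path(outdir, "probe_annotation.tsv"),
    cohort = file.path(outdir, "cohort.csv"),
    panel = file.path(outdir, "cell_reference_panel.tsv"),
    mqtl = file.path(outdir, "mqtl_table.tsv"),
    truth = file.path(outdir, "ground_truth.json")
  )
  .write_beta(cohort$birth$beta, paths[["beta_birth"]])
  .write_beta(cohort$age7$beta, paths[["beta_age7"]])

  ann <- cohort$birth$annotation
  bed <- data.frame(chrom = ann$chrom, pos = ann$pos, probe_id = ann$probe_id,
                    gene = ann$gene,
                    cross_reactive = as.integer(ann$cross_reactive),
                    control_probe = as.integer(ann$control_probe),
                    snp_at_sbe = as.integer(ann$snp_at_sbe))
  utils::write.table(bed, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$cohort, paths[["cohort"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(cohort$panel, paths[["panel"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$mqtl_table, paths[["mqtl"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- cohort$truth
  truth$genotypes <- as.data.frame(truth$genotypes)
  truth$cell_proportions <- lapply(truth$cell_proportions, as.data.frame)
  truth$first_order_factors <- as.data.frame(truth$first_order_factors)
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(paths)
}

.write_beta <- function(beta, path) {
  df <- data.frame(sample_id = rownames(beta), beta, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a cohort fixture written by \code{\link{write_fixture}}
#'
#' @param dir directory containing the fixture files.
#' @return list with \code{birth}, \code{age7} (methylome objects),
#'   \code{cohort}, \code{panel}, \code{mqtl_table}, and the raw
#'   \code{truth} list re-read from JSON.
#' @export
read_fixture <- function(dir) {
  read_beta <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$sample_id
    m
  }
  bed <- utils::read.delim(file.path(dir, "probe_annotation.tsv"),
                           stringsAsFactors = FALSE)
  ann <- data.frame(probe_id = bed$probe_id, chrom = bed$chrom, pos = bed$pos,
                    gene = ifelse(is.na(bed$gene), "", bed$gene),
                    cross_reactive = bed$cross_reactive == 1,
                    control_probe = bed$control_probe == 1,
                    snp_at_sbe = bed$snp_at_sbe == 1,
                    stringsAsFactors = FALSE)
  list(
    birth = methylome(read_beta(file.path(dir, "beta_birth.tsv")), ann, "birth"),
    age7 = methylome(read_beta(file.path(dir, "beta_age7.tsv")), ann, "age7"),
    cohort = utils::read.csv(file.path(dir, "cohort.csv"),
                             stringsAsFactors = FALSE),
    panel = utils::read.delim(file.path(dir, "cell_reference_panel.tsv"),
                              check.names = FALSE, stringsAsFactors = FALSE),
    mqtl_table = utils::read.delim(file.path(dir, "mqtl_table.tsv"),
                                   stringsAsFactors = FALSE),
    truth = jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                simplifyVector = TRUE)
  )
}
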