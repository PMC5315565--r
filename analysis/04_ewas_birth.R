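#!/usr/bin/env Rscript
# Stage 4: discovery epigenome-wide association at birth. Probe-wise OLS of
# beta values on the liability factor score, adjusting for sex and the five
# cell proportions; BH-FDR at q < 0.05; then spatially-correlated region
# calling on the p-value track (seed p 1e-4, 500 bp window).

library(methrisk)

data <- read_fixture("results/cohort")
scores <- read.csv("results/factor_scores.csv")
cells <- read.csv("results/cell_proportions_birth.csv")

kept <- filter_probes(data$birth$annotation)
covars <- data.frame(sex = data$cohort$sex, cells[, -1])
ewas <- run_ewas(data$birth, scores$liability, covars, probes = kept)
dmps <- select_dmps(ewas, 0.05)

## top table in the conventional column order
ord <- ewas[order(ewas$p), ]
top <- data.frame(Probe = ord$probe_id, Gene = ord$gene, Chr = ord$chrom,
                  Position = ord$position, `Std B` = round(ord$std_beta, 3),
                  `P-value` = signif(ord$p, 3),
                  `q-value` = signif(ord$q, 3), check.names = FALSE)
write.table(top, "results/ewas_birth.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(dmps, "results/dmps_birth.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

message(sprintf("%d probes tested; %d DMPs at q<0.05 (%d hypo / %d hyper)",
                attr(ewas, "m_total"), nrow(dmps),
                sum(dmps$std_beta < 0), sum(dmps$std_beta > 0)))
recovered <- sum(dmps$probe_id %in% data$truth$dmp_ids)
message(sprintf("%d of %d planted DMPs recovered", recovered,
                length(data$truth$dmp_ids)))

## region calling
ok <- !is.na(ewas$p)
idx <- match(ewas$probe_id[ok], data$birth$annotation$probe_id)
track <- pval_track(data$birth$annotation$chrom[idx],
                    data$birth$annotation$pos[idx], ewas$p[ok],
                    ewas$probe_id[ok])
dmrs <- call_dmrs(track, p_threshold = 1e-4, window = 500)
write.table(dmrs, "results/dmrs_birth.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
message(sprintf("%d candidate regions, %d significant after Sidak correction",
                nrow(dmrs), sum(dmrs$p_sidak < 0.05)))
message("wrote results/ewas_birth.tsv, results/dmps_birth.tsv, results/dmrs_birth.tsv")
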