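#!/usr/bin/env Rscript
# Stage 5: temporal follow-forward. Re-test the birth DMPs against the same
# liability outcome using age-7 methylation (FDR over the DMP set only),
# then quantify per-probe cross-time autocorrelation and compare the
# within-time co-methylation networks.

library(methrisk)

data <- read_fixture("results/cohort")
scores <- read.csv("results/factor_scores.csv")
cells7 <- read.csv("results/cell_proportions_age7.csv")
dmps <- read.delim("results/dmps_birth.tsv")
class(dmps) <- c("dmp_set", "data.frame")

covars <- data.frame(sex = data$cohort$sex, cells7[, -1])
ff <- follow_forward(dmps, data$age7, scores$liability, covars)
write.table(ff, "results/follow_forward_age7.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("replications at q<0.05: %d of %d; nominal (p<0.05): %d",
                attr(ff, "n_replicated"), nrow(ff),
                length(attr(ff, "nominal"))))

auto <- probe_autocorrelation(data$birth, data$age7, dmps$probe_id)
write.table(auto$per_probe, "results/autocorrelation_dmps.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
s <- auto$summary
message(sprintf("autocorrelation: r_max=%.2f, r_min=%.2f, mean |r|=%.2f, %d probes p<0.05",
                s[["r_max"]], s[["r_min"]], s[["mean_abs_r"]],
                s[["n_sig"]]))

cm1 <- comethylation_structure(data$birth, dmps$probe_id)
cm2 <- comethylation_structure(data$age7, dmps$probe_id)
cmp <- compare_structures(cm1$R, cm2$R, seed = 1)
message(sprintf("co-methylation at birth: %.0f%% of pairs q<0.05 (r in %.2f..%.2f)",
                cm1$summary[["pct_sig"]], cm1$summary[["r_min"]],
                cm1$summary[["r_max"]]))
message(sprintf("structure similarity birth vs age 7: r=%.2f (Mantel p=%.3f)",
                cmp$similarity, cmp$mantel_p))
jsonlite::write_json(list(birth = as.list(cm1$summary),
                          age7 = as.list(cm2$summary),
                          similarity = cmp$similarity,
                          mantel_p = cmp$mantel_p),
                     "results/comethylation.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote results/follow_forward_age7.tsv, results/autocorrelation_dmps.tsv, results/comethylation.json")
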