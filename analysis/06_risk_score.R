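#!/usr/bin/env Rscript
# Stage 6: cumulative weighted DNAm risk score (weights = discovery
# standardized betas applied to raw beta values), its mQTL-excluded
# variant, the prenatal-exposure screen and the age-of-onset correlations.

library(methrisk)

data <- read_fixture("results/cohort")
scores <- read.csv("results/factor_scores.csv")
dmps <- read.delim("results/dmps_birth.tsv")
class(dmps) <- c("dmp_set", "data.frame")

mrs_full <- compute_mrs(data$birth, dmps, variant = "full")
red <- exclude_mqtl_probes(dmps, data$mqtl_table)
message(sprintf("mQTL exclusion: %d probes removed (cis=%d, trans=%d)",
                attr(red, "n_removed"), attr(red, "n_cis"),
                attr(red, "n_trans")))
out <- data.frame(sample_id = mrs_full$sample_id,
                  score_full = mrs_full$score)
if (nrow(red) > 0) {
  mrs_red <- compute_mrs(data$birth, red, variant = "mqtl_excluded")
  out$score_mqtl_excluded <- mrs_red$score
  message(sprintf("full vs mQTL-excluded score: r=%.3f",
                  cor(mrs_full$score, mrs_red$score)))
}
write.csv(out, "results/risk_scores.csv", row.names = FALSE)

expos <- data.frame(
  maternal_smoking = data$cohort$maternal_smoking,
  maternal_alcohol = data$cohort$maternal_alcohol,
  maternal_risks = data$cohort$parental_risks,
  family_risks = data$cohort$interpersonal_risks,
  contextual_risks = data$cohort$contextual_risks,
  life_events = data$cohort$life_events
)
screen <- screen_exposures(mrs_full, scores$liability, expos)
write.csv(screen, "results/exposure_screen.csv", row.names = FALSE)
sig <- screen[screen$variable == "dnam_risk" & screen$q < 0.05, ]
message(sprintf("exposures correlated with DNAm risk at q<0.05: %s",
                if (nrow(sig)) paste(sig$exposure, collapse = ", ")
                else "none"))

onset_cols <- grep("^onset_age_", names(data$cohort), value = TRUE)
onset <- onset_correlation(mrs_full, data$cohort[onset_cols])
write.csv(onset, "results/onset_correlations.csv", row.names = FALSE)
for (i in seq_len(nrow(onset)))
  message(sprintf("%s: r=%.2f, p=%.3g, n_endorse=%d", onset$substance[i],
                  onset$r[i], onset$p[i], onset$n[i]))
message("wrote results/risk_scores.csv, results/exposure_screen.csv, results/onset_correlations.csv")
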