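#!/usr/bin/env Rscript
# Stage 7: path-analytic mediation. The exposures passing the screen enter a
# recursive model exposure -> DNAm risk score -> liability; indirect effects
# are a_k * b with case-resampling bootstrap percentile CIs. Per-substance
# refits use the three first-order factor scores; a winsorized sensitivity
# rerun guards against outliers.

library(methrisk)

data <- read_fixture("results/cohort")
scores <- read.csv("results/factor_scores.csv")
mrs <- read.csv("results/risk_scores.csv")
screen <- read.csv("results/exposure_screen.csv")

expos_all <- data.frame(
  maternal_smoking = data$cohort$maternal_smoking,
  maternal_alcohol = data$cohort$maternal_alcohol,
  maternal_risks = data$cohort$parental_risks,
  family_risks = data$cohort$interpersonal_risks,
  contextual_risks = data$cohort$contextual_risks,
  life_events = data$cohort$life_events
)
sig <- screen$exposure[screen$variable == "dnam_risk" & screen$q < 0.05]
if (length(sig) == 0) {
  message("no exposure passed the screen; mediation stage skipped")
  quit(save = "no", status = 0)
}
message("exposures entering the path model: ", paste(sig, collapse = ", "))

mediator <- scale(mrs$score_full)[, 1]
fit <- bootstrap_ci(expos_all[, sig, drop = FALSE], mediator,
                    scores$liability, B = 10000, seed = 1)
print(fit)
jsonlite::write_json(list(n = fit$n, B = fit$B, indirect = fit$indirect,
                          ci = fit$ci),
                     "results/mediation_fit.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
for (e in sig) {
  ci <- fit$ci[fit$ci$term == paste0("indirect_", e), ]
  message(sprintf("indirect %s -> score -> liability: b=%.3f, 95%% CI %.3f-%.3f",
                  e, ci$est, ci$lo, ci$hi))
}

## per-substance refits on the first-order factor scores
subs <- scores[, c("tobacco", "cannabis", "alcohol")]
per <- per_substance_mediation(expos_all[, sig, drop = FALSE], mediator,
                               subs, B = 2000, seed = 2)
for (s in names(per)) {
  ci <- per[[s]]$ci[per[[s]]$ci$term == paste0("indirect_", sig[1]), ]
  message(sprintf("%s: indirect b=%.3f, 95%% CI %.3f-%.3f", s, ci$est,
                  ci$lo, ci$hi))
}
jsonlite::write_json(lapply(per, function(f) list(indirect = f$indirect,
                                                  ci = f$ci)),
                     "results/mediation_per_substance.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

## winsorized sensitivity for any outcome with a > 3 SD outlier
for (s in names(subs)) {
  w <- winsorize(subs[[s]], k = 3)
  if (w$n_modified > 0) {
    refit <- fit_path_model(expos_all[, sig, drop = FALSE], mediator,
                            w$values)
    message(sprintf("%s: %d outlier(s) winsorized; indirect %s b=%.3f",
                    s, w$n_modified, sig[1],
                    refit$indirect$est[refit$indirect$exposure == sig[1]]))
  }
}
message("wrote results/mediation_fit.json, results/mediation_per_substance.json")
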