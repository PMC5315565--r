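#!/usr/bin/env Rscript
# Stage 3: estimate blood cell-type proportions at both timepoints by
# constrained projection onto the reference panel; these are covariates in
# every probe-wise model.

library(methrisk)

data <- read_fixture("results/cohort")

for (tp in c("birth", "age7")) {
  pr <- estimate_proportions(data[[tp]], data$panel)
  out <- data.frame(sample_id = rownames(pr), pr)
  write.csv(out, sprintf("results/cell_proportions_%s.csv", tp),
            row.names = FALSE)
  message(sprintf("%s: mean proportions %s", tp,
                  paste(sprintf("%s=%.2f", colnames(pr), colMeans(pr)),
                        collapse = ", ")))
}
message("wrote results/cell_proportions_{birth,age7}.csv")
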