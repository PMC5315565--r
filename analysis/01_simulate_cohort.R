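#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-timepoint cohort at desk scale
# (500 samples x 20,000 probes, 65 planted DMPs of which 5 under mQTL
# control) and persist it as plain-text files for the later stages.

library(methrisk)

cfg <- sim_config(seed = 1)   # defaults are the study-like conditions
cohort <- simulate_cohort(cfg)

paths <- write_fixture(cohort, "results/cohort")

message(sprintf("cohort: %d samples x %d probes at two timepoints",
                nrow(cohort$birth$beta), ncol(cohort$birth$beta)))
message(sprintf("planted: %d DMPs (%d under mQTL control), %d smoking probes",
                length(cohort$truth$dmp_ids),
                length(cohort$truth$mqtl_probe_ids),
                length(cohort$truth$exposure_probe_ids$maternal_smoking)))
message(sprintf("%d%% female; %d%% prenatally smoke-exposed",
                round(100 * mean(cohort$cohort$sex)),
                round(100 * mean(cohort$cohort$maternal_smoking))))
message("written: ", paste(basename(paths), collapse = ", "))
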