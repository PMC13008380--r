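#!/usr/bin/env Rscript
# Stage 2 — parcellated-level preprocessing and motion QC.
#
# Per subject: regression of the 24 motion parameters plus a surrogate global
# signal, 0.008-0.08 Hz rectangular bandpass, respiratory-notched (0.31-0.43
# Hz) framewise displacement, and the three-rule exclusion (mean FD > 0.3 mm;
# > 20% of frames above 0.2 mm; any frame > 5 mm).

suppressMessages(library(couplingbench))

cohort <- read_cohort("results/cohort")
prep <- prep_cohort(cohort$series, cohort$motion, exclusion = "strict")

utils::write.csv(prep$exclusions, "results/exclusion_report.csv", row.names = FALSE)
dir.create("scratch/analysis", recursive = TRUE, showWarnings = FALSE)
saveRDS(list(prep = prep, cohort = cohort), "scratch/analysis/prep.rds", version = 2)

message(sprintf(
  "retained %d / %d subjects (excluded: %s)",
  length(prep$retained), nrow(prep$exclusions),
  paste(prep$exclusions$subject_id[prep$exclusions$excluded], collapse = ", ")
))
message(sprintf(
  "mean FD after notch filtering: median %.3f mm", stats::median(prep$mean_fd)
))
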