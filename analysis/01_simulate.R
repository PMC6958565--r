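#!/usr/bin/env Rscript
# Simulate the study cohort: 16 young (HYV) and 19 elderly (HEV) synthetic
# subjects, four cardiac-gated PC-MRI planes each, parameterized from the
# reference group means/SDs. Writes the generator's ground truth and the
# configured per-subject draws; the cine stacks themselves are rasterized
# on the fly in 02_quantify.R (they are reproducible from the scene seeds).
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(cranioflow))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

cohort <- make_cohort(16, 19, seed = seed)
saveRDS(cohort, file.path("results", "cohort.rds"))
write.csv(cohort$truth, file.path("results", "truth.csv"), row.names = FALSE)
write.csv(cohort$configured, file.path("results", "configured.csv"),
          row.names = FALSE)

cat(sprintf("Simulated %d subjects (seed %d).\n",
            nrow(cohort$truth), seed))
for (g in c("HYV", "HEV")) {
  tr <- cohort$truth[cohort$truth$group == g, ]
  cat(sprintf("  %s: n = %d, true ExtraACBF %.0f +/- %.0f ml/min, spinal CSF SV %.2f ml/cc\n",
              g, nrow(tr), mean(tr$extra_acbf), sd(tr$extra_acbf),
              mean(tr$spinal_csf_sv)))
}
cat("Ground truth in results/truth.csv; scenes in results/cohort.rds\n")
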