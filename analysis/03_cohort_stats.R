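#!/usr/bin/env Rscript
# Statistical layer over the quantified cohort: per-metric outlier
# exclusion (mean +/- 1.5 IQR), group summaries, Shapiro-gated between-group
# and paired extra-vs-intra comparisons, the stroke-volume correlation
# panel, and the derived drainage ratios. Writes the report tables and
# markdown under results/report/.
#
# Usage: Rscript analysis/03_cohort_stats.R   (after 02_quantify.R)

suppressPackageStartupMessages(library(cranioflow))

metrics <- read.csv(file.path("results", "metrics.csv"))
report <- build_report(metrics)
write_report(report, file.path("results", "report"))

cat("Group summaries (mean +/- SD (min-max)), between-group p:\n")
s <- report$summary
for (i in seq_len(nrow(s)))
  cat(sprintf("  %-26s HYV %-28s HEV %-28s p = %s %s\n",
              s$parameter[i], s$HYV_summary[i], s$HEV_summary[i],
              format(signif(s$p_between[i], 2)), s$stars_between[i]))

cat("\nDerived ratios:\n")
r <- report$ratios
for (i in seq_len(nrow(r)))
  cat(sprintf("  %s %-58s %.1f%%\n", r$group[i], r$ratio[i], r$value[i]))

if (!is.null(report$exclusions)) {
  cat(sprintf("\n%d aberrant values excluded (see results/report/exclusions.csv)\n",
              nrow(report$exclusions)))
}
cat("\nFull report under results/report/ (report.md + CSV tables)\n")
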