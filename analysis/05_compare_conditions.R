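#!/usr/bin/env Rscript
# Paired condition comparison: read the per-capillary results of
# 03_analyze_capillaries.R, pair each capillary's dry and cool-immersion
# measurements, and summarize the temperature effect as per-capillary
# percent changes and group mean +/- s.e.m.

library(plmox)

if (!file.exists("results/capillary_results.csv")) {
  stop("run analysis/03_analyze_capillaries.R first")
}
results <- utils::read.csv("results/capillary_results.csv")

cmp <- compare_conditions(results, baseline = "awake_dry_37C")
print(cmp)

cat("\nMean percent change, dry -> cool immersion (capillary as unit):\n")
ch <- cmp$changes
for (m in unique(ch$metric)) {
  v <- ch$percent_change[ch$metric == m]
  cat(sprintf("  %-22s %+6.1f %% (s.e.m. %4.1f, n = %d)\n",
              m, mean(v), sd(v) / sqrt(length(v)), length(v)))
}

utils::write.csv(cmp$summary, "results/comparison_summary.csv",
                 row.names = FALSE)
utils::write.csv(cmp$changes, "results/comparison_changes.csv",
                 row.names = FALSE)
cat("\nwrote results/comparison_summary.csv and results/comparison_changes.csv\n")
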