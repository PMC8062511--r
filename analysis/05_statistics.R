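#!/usr/bin/env Rscript
# Statistics and report over the factorial results written by
# 04_factorial.R: grouped summaries with figures, design comparisons per
# metric, and the 12-peak vs 9-peak expansion-difference table.

suppressPackageStartupMessages({
  library(stentmech)
  library(readr)
})

res_path <- file.path("analysis", "results", "factorial_results.csv")
if (!file.exists(res_path)) stop("run analysis/04_factorial.R first")
tab <- readr::read_csv(res_path, show_col_types = FALSE)

out_dir <- file.path("analysis", "results", "report")
make_report(tab, out_dir, plots = TRUE)

for (metric in c("msd", "ccd", "prolapse", "sar", "hoop_force",
                 "radial_strength")) {
  cmp <- compare_groups(tab, metric, grouping = "design")
  cat(sprintf("\n== %s by design ==\n", metric))
  print(cmp)
  chosen <- if (cmp$method == "anova") cmp$anova else cmp$friedman
  print(as.data.frame(chosen$pairwise))
}

pct <- expansion_difference(tab, "MEGATRON_12", "MEGATRON_9")
readr::write_csv(pct, file.path(out_dir, "msd_pct_diff_12_vs_9.csv"))
cat("\n== MSD % difference (12-peak vs 9-peak, by diameter and plaque) ==\n")
print(as.data.frame(pct))
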