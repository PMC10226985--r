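#!/usr/bin/env Rscript
# Step 5: statistical report. Groups the per-cell records by inner/outer
# position, summarizes each metric (median, IQR, mean, SD) and runs the
# normality-routed comparison (t-test / Mann-Whitney for two groups, with
# ANOVA+Dunnett / Kruskal-Wallis+Dunn for multi-group data) for L:N ratio,
# meshwork density and distance to the embryo center of mass.
# Writes results/report/report.json.

suppressMessages(library(laminmorph))

cr <- read.csv("results/records/records.csv")
out <- "results/report"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

metrics <- c("ln_ratio", "mesh_density", "distance_to_embryo_cm",
             "apical_fraction", "aspect_ratio")
metrics <- intersect(metrics, names(cr))

summary_tab <- summarize_groups(cr, "position_class", metrics)
write.csv(summary_tab, file.path(out, "group_summary.csv"),
          row.names = FALSE)

comparisons <- list()
for (m in metrics) {
  g <- split(cr[[m]], cr$position_class)
  if (length(g) == 2 && all(lengths(g) >= 3)) {
    cmp <- route_and_test(g)
    comparisons[[m]] <- list(test_used = cmp$test_used,
                             statistic = cmp$statistic,
                             p_value = cmp$p_value, flags = cmp$flags)
    message(sprintf("%-22s %-14s p = %.4g", m, cmp$test_used, cmp$p_value))
  }
}
jsonlite::write_json(list(summary = summary_tab, comparisons = comparisons),
                     file.path(out, "report.json"), auto_unbox = TRUE,
                     digits = NA)
message("wrote ", out)
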