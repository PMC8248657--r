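#!/usr/bin/env Rscript
# Stage 2 — clean the longitudinal tables and consolidate to one record per
# subject carrying the percentage weight change between baseline and last
# follow-up. Cleaning drops rows with missing analysis values, then rows
# whose screened clinical scores (total functional capacity, independence,
# irritability, motor, depression) fall outside the Tukey boxplot fence.

suppressPackageStartupMessages(library(hdwtrules))

cohort <- read_cohort("results/cohort.csv")
records <- NULL
for (g in unique(cohort$group)) {
  rec <- preprocess_cohort(cohort[cohort$group == g, ])
  counts <- attr(rec, "counts")
  cat(sprintf("[%s] %d rows in; %d dropped missing; %d dropped as outliers; %d subjects retained (%d excluded: no baseline or no follow-up)\n",
              g, counts[["rows_in"]], counts[["rows_dropped_missing"]],
              counts[["rows_dropped_outlier"]],
              counts[["subjects_retained"]], counts[["subjects_excluded"]]))
  records <- rbind(records, rec)
}

utils::write.csv(records, "results/records.csv", row.names = FALSE)
cat("consolidated records written to results/records.csv\n")
cat(sprintf("weight change: mean %.2f%%, sd %.2f%%, range [%.1f%%, %.1f%%]\n",
            mean(records$delta_w), sd(records$delta_w),
            min(records$delta_w), max(records$delta_w)))
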