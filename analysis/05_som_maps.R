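#!/usr/bin/env Rscript
# Stage 5 — self-organizing map summaries per group: a 4x4 map trained on
# the categorized records (weight category included, so the maps show how
# weight change co-locates with factor profiles), then the count plot, the
# per-node weight-category distribution and the codebook profiles.

suppressPackageStartupMessages(library(hdwtrules))

kb_all <- utils::read.csv("results/kb.csv", stringsAsFactors = FALSE)
for (g in unique(kb_all$group)) {
  kb <- kb_all[kb_all$group == g, ]
  model <- train_som(kb, som_config(epochs = 100, seed = 7))
  qe <- model$quantization_error
  cat(sprintf("[%s] SOM trained on %d records; quantization error %.3f -> %.3f over %d epochs\n",
              g, nrow(kb), qe[1], qe[length(qe)], length(qe)))
  counts <- node_counts(model, kb)
  cat(sprintf("    records per node: min %d, max %d, empty nodes: %d\n",
              min(counts$count), max(counts$count),
              sum(counts$count == 0)))
  utils::write.csv(counts, sprintf("results/som_counts_%s.csv", g),
                   row.names = FALSE)
  utils::write.csv(node_class_distribution(model, kb, "wtCat"),
                   sprintf("results/som_wtcat_%s.csv", g), row.names = FALSE)
  utils::write.csv(codes_profile(model),
                   sprintf("results/som_codes_%s.csv", g), row.names = FALSE)
}
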