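#!/usr/bin/env Rscript
# Stage 4 — mine class association rules with the severe weight-loss
# categories (wtCat -3 and -2) as consequents: Apriori with minimum
# confidence 0.9, rule length 2-5, minimum support 0.01, followed by
# redundant-rule elimination. Writes per-group rule tables and antecedent
# histograms.

suppressPackageStartupMessages(library(hdwtrules))

kb_all <- utils::read.csv("results/kb.csv", stringsAsFactors = FALSE)
for (g in unique(kb_all$group)) {
  kb <- kb_all[kb_all$group == g, ]
  for (wc in c(-3L, -2L)) {
    consequent <- sprintf("wtCat=%d", wc)
    rules <- mine_class_rules(kb, consequent, min_confidence = 0.9,
                              min_len = 2, max_len = 5, min_support = 0.01)
    pruned <- eliminate_redundant(rules)
    export_rule_report(pruned, sprintf("results/rules_%s_wtCat%d.csv", g, wc))
    export_histogram_report(pruned,
                            sprintf("results/antecedent_hist_%s_wtCat%d.csv",
                                    g, wc))
    cat(sprintf("[%s] %s: %d rules mined, %d after redundancy pruning\n",
                g, consequent, nrow(rules), nrow(pruned)))
    if (nrow(pruned)) {
      top <- utils::head(as.data.frame(pruned), 3)
      for (i in seq_len(nrow(top))) {
        cat(sprintf("    {%s} => %s  conf %.3f  lift %.1f  chi2 %.1f\n",
                    gsub(";", ", ", top$antecedent[i]), consequent,
                    top$confidence[i], top$lift[i], top$chi2[i]))
      }
    }
  }
}
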