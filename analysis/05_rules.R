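#!/usr/bin/env Rscript
# Stage 5: association rules.
#
# For each hippocampal ROI, derives all (k-1)->1 rules from the itemsets
# mined at s = 0.5 with supports recomputed on the transaction database,
# prints the top 2-item rules (confidence displayed at 2 dp, weak rules
# flagged "--"), and walks the prefix confidence chain of the largest FI.

library(snpfim)

pvals <- read_matrix_tsv("results/pvalue_matrix.tsv")
roi_map <- read_roi_map("results/data/roi_map.tsv")

for (lab in c("hippocampus_L", "hippocampus_R")) {
  td <- build_transactions(subset_by_roi(pvals, roi_map, lab), alpha = 0.05)
  res <- eclat(td, 0.5)
  rules <- generate_rules(res, td, min_confidence = 0.8)
  write_rules_tsv(rules, sprintf("results/rules_%s.tsv", lab))
  two <- rules[rules$k == 2, ]
  cat("\n==", lab, ": top 2-item rules (of", nrow(rules), "rules at s = 0.5) ==\n")
  print(head(two[c("antecedent", "consequent", "support_a", "support_ab",
                   "display")], 6), row.names = FALSE)
  big <- res[res$k == max(res$k), ][1, ]
  items <- strsplit(big$items, ";")[[1]]
  if (length(items) >= 2) {
    cat("prefix confidence chain of the top", big$k, "item FI:\n")
    print(rule_chain(td, items)[c("antecedent", "consequent", "display")],
          row.names = FALSE)
  }
}
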