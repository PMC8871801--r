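#!/usr/bin/env Rscript
# Stage 3: transactionalization.
#
# Every voxel becomes a transaction holding the SNPs significant there
# (p <= 0.05, no multiplicity correction: recurrence across voxels is the
# filter). One transaction database per ROI, exported as FIMI baskets, plus
# per-item support tables (top-10 printed, the coverage-table view).

library(snpfim)

pvals <- read_matrix_tsv("results/pvalue_matrix.tsv")
roi_map <- read_roi_map("results/data/roi_map.tsv")

for (lab in sort(unique(roi_map$label))) {
  sub <- subset_by_roi(pvals, roi_map, lab)
  td <- build_transactions(sub, alpha = 0.05)
  write_basket(td, sprintf("results/transactions_%s.basket", lab))
  st <- support_table(td)
  write.table(st, sprintf("results/support_%s.tsv", lab), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("\n==", lab, ": TD_num =", td$td_num, "voxels ==\n")
  print(head(st, 10), row.names = FALSE)
}
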