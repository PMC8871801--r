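#!/usr/bin/env Rscript
# Stage 6: ROI activation.
#
# Takes the most frequent SNP overall and asks which ROIs it "activates":
# within each ROI, rank voxels by -log10(p) for that SNP, keep the top 20%,
# and require all of them significant at p <= 0.05.

library(snpfim)

pvals <- read_matrix_tsv("results/pvalue_matrix.tsv")
roi_map <- read_roi_map("results/data/roi_map.tsv")

td_all <- build_transactions(pvals, alpha = 0.05)
top_snp <- support_table(td_all)$item[1]
cat("most frequent SNP over all", td_all$td_num, "voxels:", top_snp, "\n\n")

act <- activated_rois(pvals, roi_map, top_snp, top_frac = 0.2, alpha = 0.05)
write.table(as.data.frame(act), "results/activation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(as.data.frame(act), row.names = FALSE)
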