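#!/usr/bin/env Rscript
# Stage 2: QC and voxelwise GWAS.
#
# Hardy-Weinberg filter at p_HW >= 1e-6, then one OLS fit per (SNP, voxel)
# pair with covariate adjustment, yielding the SNP x voxel p-value matrix.

library(snpfim)

g <- read_matrix_tsv("results/data/genotypes.tsv")
y <- read_matrix_tsv("results/data/phenotypes.tsv")
x <- read_matrix_tsv("results/data/covariates.tsv")

hwe <- hwe_filter(g, threshold = 1e-6)
write.table(hwe$results, "results/hwe_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("HWE filter: kept", length(hwe$kept), "of", ncol(g), "SNPs\n")
g <- g[, hwe$kept, drop = FALSE]

pvals <- run_vgwas(g, y, x)
write_matrix_tsv(pvals, "results/pvalue_matrix.tsv")

cat("p-value matrix:", nrow(pvals), "SNPs x", ncol(pvals), "voxels\n")
cat("fraction p <= 0.05 overall:", round(mean(pvals <= 0.05), 4), "\n")
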