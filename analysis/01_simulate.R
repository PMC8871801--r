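#!/usr/bin/env Rscript
# Stage 1: generate the synthetic imaging-genetics study.
#
# 600 subjects, 100 candidate SNPs, 1183 voxels in four ROIs (left/right
# hippocampus at the familiar ~280/~300-voxel scale, an insula, and a
# background region). Two multi-SNP effect blocks are planted: SNPs 1-5 on
# 70% of the left hippocampus (beta = 1.0 per minor allele) and SNPs 4-8 on
# 60% of the right hippocampus (beta = 0.8), so the two ROIs share part of
# their frequent SNP sets. Three covariates (age/education/PC stand-ins)
# carry real effects and must be adjusted away downstream.

library(snpfim)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

roi_sizes <- c(hippocampus_L = 281L, hippocampus_R = 302L,
               insula = 200L, background = 400L)
n_voxels <- sum(roi_sizes)
roi_map <- data.frame(
  voxel_id = sprintf("vox%05d", seq_len(n_voxels)),
  label = rep(names(roi_sizes), roi_sizes)
)
vox_idx <- split(seq_len(n_voxels), roi_map$label)

blocks <- list(
  effect_block(1:5, vox_idx$hippocampus_L[seq_len(ceiling(0.7 * 281))], beta = 1.0),
  effect_block(4:8, vox_idx$hippocampus_R[seq_len(ceiling(0.6 * 302))], beta = 0.8)
)

cfg <- sim_config(
  n_subjects = 600, n_snps = 100, n_voxels = n_voxels,
  mafs = 0.3, blocks = blocks, noise_sd = 1,
  n_covariates = 3, covariate_betas = c(0.3, -0.2, 0.1),
  seed = 20260928
)

study <- simulate_study(cfg)
write_matrix_tsv(study$genotypes, file.path(out, "genotypes.tsv"))
write_matrix_tsv(study$phenotypes, file.path(out, "phenotypes.tsv"))
write_matrix_tsv(study$covariates, file.path(out, "covariates.tsv"))
write_roi_map(roi_map, file.path(out, "roi_map.tsv"))
jsonlite::write_json(
  list(n_subjects = cfg$n_subjects, n_snps = cfg$n_snps,
       n_voxels = cfg$n_voxels, noise_sd = cfg$noise_sd,
       covariate_betas = cfg$covariate_betas, seed = cfg$seed,
       roi_sizes = as.list(roi_sizes),
       blocks = lapply(cfg$blocks, unclass)),
  file.path(out, "sim_config.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
)

cat("simulated", cfg$n_subjects, "subjects x", cfg$n_snps, "SNPs x",
    cfg$n_voxels, "voxels;", length(blocks), "planted blocks\n")
cat("planted SNP sets:",
    paste(sapply(blocks, function(b) paste0("{", paste(sprintf("snp%04d", b$snp_ids),
                                                       collapse = ","), "}")),
          collapse = " and "), "\n")
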