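Package: snpfim
Title: Frequent Itemset Mining of SNP Sets from Voxelwise GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering co-significant SNP sets in imaging
    genetics. Voxelwise genome-wide association (one linear regression per
    SNP-voxel pair, with covariates) yields a SNP-by-voxel p-value matrix;
    thresholding turns each voxel into a transaction whose items are the SNPs
    significant there; FP-Growth and Eclat mine frequent SNP itemsets from the
    transactional database; association rules with confidence quantify the
    dependence between SNPs in an itemset; and a top-fraction voxel criterion
    decides which anatomical regions a SNP activates. Includes a synthetic-data
    generator (Hardy-Weinberg genotypes, covariates, voxel phenotypes with
    planted multi-SNP/multi-voxel effects) so the whole pipeline is testable
    without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
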