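#' Define a planted effect block
#'
#' An effect block ties a set of SNPs to a set of voxels: every minor allele
#' of every SNP in the block adds `beta` to the phenotype of every voxel in
#' the block. Downstream, the block's SNPs become co-significant across the
#' block's voxels and should be recovered as a frequent itemset.
#'
#' @param snp_ids Integer indices (1-based) of the SNPs carrying the effect.
#' @param voxel_ids Integer indices (1-based) of the voxels receiving it.
#' @param beta Additive effect per minor allele, in phenotype units.
#' @return An object of class `effect_block`.
#' @export
effect_block <- function(snp_ids, voxel_ids, beta) {
  snp_ids <- as.integer(snp_ids)
  voxel_ids <- as.integer(voxel_ids)
  if (length(snp_ids) == 0L || anyNA(snp_ids) || any(snp_ids < 1L)) {
    stop("snp_ids must be a non-empty set of positive indices")
  }
  if (length(voxel_ids) == 0L || anyNA(voxel_ids) || any(voxel_ids < 1L)) {
    stop("voxel_ids must be a non-empty set of positive indices")
  }
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  structure(
    list(snp_ids = sort(unique(snp_ids)),
         voxel_ids = sort(unique(voxel_ids)),
         beta = as.double(beta)),
    class = "effect_block"
  )
}

check_blocks <- function(blocks, n_snps, n_voxels) {
  for (b in blocks) {
    if (!inherits(b, "effect_block")) stop("blocks must be effect_block objects")
    if (max(b$snp_ids) > n_snps) {
      stop("block SNP index ", max(b$snp_ids), " out of range (n_snps = ", n_snps, ")")
    }
    if (max(b$voxel_ids) > n_voxels) {
      stop("block voxel index ", max(b$voxel_ids), " out of range (n_voxels = ", n_voxels, ")")
    }
  }
  invisible(blocks)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study into one validated object.
#' `mafs` may be a single value (recycled) or one minor-allele frequency per
#' SNP, each in (0, 0.5].
#'
#' @param n_subjects,n_snps,n_voxels Problem dimensions.
#' @param mafs Minor-allele frequencies, length 1 or `n_snps`.
#' @param blocks List of [effect_block()] objects (may be empty).
#' @param noise_sd Residual SD of the voxel phenotypes.
#' @param n_covariates Number of standard-normal covariate columns.
#' @param covariate_betas Optional effects of the covariates on every voxel
#'   (length `n_covariates`); defaults to zero.
#' @param seed Integer seed; expanded into independent per-stage substreams.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects, n_snps, n_voxels, mafs = 0.3,
                       blocks = list(), noise_sd = 1, n_covariates = 0L,
                       covariate_betas = NULL, seed = 1L) {
  stopifnot(n_subjects >= 1, n_snps >= 1, n_voxels >= 1,
            noise_sd >= 0, n_covariates >= 0)
  if (length(mafs) == 1L) mafs <- rep(mafs, n_snps)
  if (length(mafs) != n_snps) stop("mafs must have length 1 or n_snps")
  check_mafs(mafs)
  check_blocks(blocks, n_snps, n_voxels)
  if (is.null(covariate_betas)) covariate_betas <- rep(0, n_covariates)
  if (length(covariate_betas) != n_covariates) {
    stop("covariate_betas must have length n_covariates")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
         n_voxels = as.integer(n_voxels), mafs = as.double(mafs),
         blocks = blocks, noise_sd = as.double(noise_sd),
         n_covariates = as.integer(n_covariates),
         covariate_betas = as.double(covariate_betas),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

check_mafs <- function(mafs) {
  bad <- which(!is.finite(mafs) | mafs <= 0 | mafs > 0.5)
  if (length(bad)) {
    stop("invalid MAF for SNP ", bad[1L], ": ", mafs[bad[1L]],
         " (must lie in (0, 0.5])")
  }
  invisible(mafs)
}

snp_names <- function(n) sprintf("snp%04d", seq_len(n))
voxel_names <- function(n) sprintf("vox%05d", seq_len(n))
subject_names <- function(n) sprintf("subj%04d", seq_len(n))

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Draws 0/1/2 minor-allele dosages independently per SNP with
#' P(2) = q^2, P(1) = 2q(1-q), P(0) = (1-q)^2 for minor-allele frequency q.
#' No linkage disequilibrium is simulated.
#'
#' @param n_subjects Number of subjects (rows).
#' @param mafs Vector of per-SNP minor-allele frequencies in (0, 0.5].
#' @param seed Integer seed.
#' @return Integer matrix, subjects x SNPs, with dimnames.
#' @export
simulate_genotypes <- function(n_subjects, mafs, seed = 1L) {
  stopifnot(n_subjects >= 1)
  check_mafs(mafs)
  n_snps <- length(mafs)
  with_stage_seed(seed, "genotypes", {
    g <- vapply(mafs, function(q) {
      sample(0:2, n_subjects, replace = TRUE,
             prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    }, integer(n_subjects))
    g <- matrix(as.integer(g), nrow = n_subjects, ncol = n_snps,
                dimnames = list(subject_names(n_subjects), snp_names(n_snps)))
    g
  })
}

#' Simulate covariates
#'
#' Standard-normal covariate columns (stand-ins for age, education, genotype
#' principal components, ...). Returned as a numeric matrix; columns are
#' consumed by [run_vgwas()], never interpreted.
#'
#' @param n_subjects Number of subjects.
#' @param n_covariates Number of covariate columns.
#' @param seed Integer seed.
#' @return Numeric matrix, subjects x covariates (0 columns allowed).
#' @export
simulate_covariates <- function(n_subjects, n_covariates, seed = 1L) {
  stopifnot(n_subjects >= 1, n_covariates >= 0)
  with_stage_seed(seed, "covariates", {
    matrix(stats::rnorm(n_subjects * n_covariates), nrow = n_subjects,
           dimnames = list(subject_names(n_subjects),
                           if (n_covariates) sprintf("cov%02d", seq_len(n_covariates))))
  })
}

#' Simulate voxel phenotypes with planted additive SNP effects
#'
#' Each voxel's phenotype is the sum, over every effect block containing that
#' voxel, of `beta` times the dosages of the block's SNPs, plus an optional
#' covariate term and Gaussian noise:
#' `y[i, v] = sum_b sum_j beta_b * g[i, j] + x[i, ] %*% covariate_betas + e`,
#' `e ~ N(0, noise_sd^2)`.
#'
#' @param genotypes Subjects x SNPs dosage matrix.
#' @param n_voxels Number of voxel columns to generate.
#' @param blocks List of [effect_block()] objects.
#' @param noise_sd Residual standard deviation (>= 0).
#' @param covariates Optional subjects x covariates matrix.
#' @param covariate_betas Effects of the covariates, applied to every voxel.
#' @param seed Integer seed.
#' @return Numeric matrix, subjects x voxels, with dimnames.
#' @export
simulate_phenotypes <- function(genotypes, n_voxels, blocks = list(),
                                noise_sd = 1, covariates = NULL,
                                covariate_betas = NULL, seed = 1L) {
  stopifnot(is.matrix(genotypes), n_voxels >= 1, noise_sd >= 0)
  n <- nrow(genotypes)
  check_blocks(blocks, ncol(genotypes), n_voxels)
  y <- matrix(0, nrow = n, ncol = n_voxels,
              dimnames = list(rownames(genotypes), voxel_names(n_voxels)))
  for (b in blocks) {
    signal <- genotypes[, b$snp_ids, drop = FALSE] %*% rep(b$beta, length(b$snp_ids))
    y[, b$voxel_ids] <- y[, b$voxel_ids] + as.vector(signal)
  }
  if (!is.null(covariates) && ncol(covariates) > 0) {
    if (nrow(covariates) != n) stop("covariates rows must match genotypes rows")
    if (is.null(covariate_betas)) covariate_betas <- rep(0, ncol(covariates))
    if (length(covariate_betas) != ncol(covariates)) {
      stop("covariate_betas must have one entry per covariate column")
    }
    y <- y + as.vector(covariates %*% covariate_betas)
  }
  if (noise_sd > 0) {
    y <- y + with_stage_seed(seed, "phenotype_noise", {
      matrix(stats::rnorm(n * n_voxels, sd = noise_sd), nrow = n)
    })
  }
  y
}

#' Simulate a SNP x voxel p-value matrix directly
#'
#' Shortcut generator for the mining layer: cells outside every block are
#' Uniform(0, 1) (a calibrated null), cells inside a block are
#' Uniform(0, alpha), i.e. guaranteed significant at threshold `alpha`. The
#' thresholding step only sees the indicator p <= alpha, so this is the
#' simplest shape that makes a block's SNPs co-significant on its voxels.
#'
#' @param n_snps,n_voxels Matrix dimensions.
#' @param blocks List of [effect_block()] objects.
#' @param alpha Significance ceiling for planted cells, in (0, 1).
#' @param seed Integer seed.
#' @return Numeric matrix, SNPs x voxels, entries in \[0, 1\].
#' @export
simulate_pvalue_matrix <- function(n_snps, n_voxels, blocks = list(),
                                   alpha = 0.05, seed = 1L) {
  stopifnot(n_snps >= 1, n_voxels >= 1, alpha > 0, alpha < 1)
  check_blocks(blocks, n_snps, n_voxels)
  with_stage_seed(seed, "pvalue_matrix", {
    p <- matrix(stats::runif(n_snps * n_voxels), nrow = n_snps,
                dimnames = list(snp_names(n_snps), voxel_names(n_voxels)))
    for (b in blocks) {
      idx <- as.matrix(expand.grid(b$snp_ids, b$voxel_ids))
      p[idx] <- stats::runif(nrow(idx), 0, alpha)
    }
    p
  })
}

#' Simulate a full synthetic study
#'
#' Runs the genotype, covariate and phenotype generators from one
#' [sim_config()], using independent seed substreams per stage (so changing
#' `n_voxels` does not perturb the genotype draws).
#'
#' @param config A [sim_config()] object.
#' @return List with elements `genotypes`, `covariates`, `phenotypes`,
#'   and the `config` echoed back.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- simulate_genotypes(config$n_subjects, config$mafs, seed = config$seed)
  x <- simulate_covariates(config$n_subjects, config$n_covariates, seed = config$seed)
  y <- simulate_phenotypes(g, config$n_voxels, blocks = config$blocks,
                           noise_sd = config$noise_sd, covariates = x,
                           covariate_betas = config$covariate_betas,
                           seed = config$seed)
  list(genotypes = g, covariates = x, phenotypes = y, config = config)
}
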