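#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' One-degree-of-freedom chi-square test of the observed genotype counts
#' against the Hardy-Weinberg expectation computed from the sample allele
#' frequency. Expected-zero cells (monomorphic SNPs) contribute nothing, so a
#' monomorphic SNP has statistic 0 and p = 1.
#'
#' @param n0,n1,n2 Counts of dosage-0, dosage-1 and dosage-2 genotypes
#'   (vectorized).
#' @return Data frame with columns `n0`, `n1`, `n2`, `chisq`, `p_hw`.
#' @export
hwe_test <- function(n0, n1, n2) {
  stopifnot(length(n0) == length(n1), length(n1) == length(n2),
            all(n0 >= 0), all(n1 >= 0), all(n2 >= 0))
  n <- n0 + n1 + n2
  if (any(n == 0)) stop("SNP with no observed genotypes")
  q <- (2 * n2 + n1) / (2 * n)
  e0 <- n * (1 - q)^2
  e1 <- n * 2 * q * (1 - q)
  e2 <- n * q^2
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  chisq <- term(n0, e0) + term(n1, e1) + term(n2, e2)
  data.frame(n0 = n0, n1 = n1, n2 = n2, chisq = chisq,
             p_hw = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Filter SNPs by Hardy-Weinberg equilibrium
#'
#' Standard genotype QC step: a SNP is kept iff its HWE chi-square p-value is
#' at least `threshold` (default 1e-6, the conventional GWAS cutoff).
#'
#' @param genotypes Subjects x SNPs dosage matrix with column names.
#' @param threshold Keep SNPs with `p_hw >= threshold`; in (0, 1).
#' @return List with `kept` (character vector of SNP ids) and `results`
#'   (per-SNP data frame: counts, statistic, p-value, kept flag).
#' @export
hwe_filter <- function(genotypes, threshold = 1e-6) {
  stopifnot(is.matrix(genotypes), threshold > 0, threshold < 1)
  if (anyNA(genotypes)) stop("missing genotypes are not supported; impute first")
  n0 <- colSums(genotypes == 0L)
  n1 <- colSums(genotypes == 1L)
  n2 <- colSums(genotypes == 2L)
  res <- hwe_test(n0, n1, n2)
  res <- cbind(snp_id = colnames(genotypes), res)
  res$kept <- res$p_hw >= threshold
  rownames(res) <- NULL
  list(kept = res$snp_id[res$kept], results = res)
}

#' Voxelwise GWAS: per (SNP, voxel) linear association with covariates
#'
#' For every pair (SNP j, voxel v), fits ordinary least squares of
#' `phenotypes[, v]` on `[intercept, genotypes[, j], covariates]` and records
#' the two-sided p-value of the genotype coefficient's t-statistic.
#'
#' Implemented via Frisch-Waugh-Lovell: genotypes and phenotypes are
#' residualized once against `[intercept, covariates]`, after which each pair
#' reduces to a simple regression whose t-test (on n - n_covariates - 2
#' degrees of freedom) is identical to the genotype coefficient's t-test in
#' the full model. This turns S x V model fits into one matrix
#' cross-product.
#'
#' Monomorphic (zero-variance) SNPs carry no association evidence: their row
#' is set to p = 1 with a warning. Constant phenotype columns likewise yield
#' p = 1 for that column.
#'
#' @param genotypes Subjects x SNPs dosage matrix.
#' @param phenotypes Subjects x voxels numeric matrix.
#' @param covariates Optional subjects x covariates numeric matrix; must be
#'   full rank together with the intercept.
#' @return Numeric SNPs x voxels matrix of p-values in \[0, 1\].
#' @export
run_vgwas <- function(genotypes, phenotypes, covariates = NULL) {
  stopifnot(is.matrix(genotypes), is.matrix(phenotypes))
  n <- nrow(genotypes)
  if (nrow(phenotypes) != n) stop("phenotypes rows must match genotypes rows")
  if (!is.null(covariates) && ncol(covariates) == 0L) covariates <- NULL
  if (!is.null(covariates) && nrow(covariates) != n) {
    stop("covariates rows must match genotypes rows")
  }
  x <- cbind(rep(1, n), covariates)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    stop("covariate matrix is rank deficient (rank ", qx$rank,
         " < ", ncol(x), " columns incl. intercept)")
  }
  df <- n - ncol(x) - 1L
  if (df < 1L) stop("not enough subjects for the model degrees of freedom")

  gr <- qr.resid(qx, genotypes)
  yr <- qr.resid(qx, phenotypes)
  ssg <- colSums(gr^2)
  ssy <- colSums(yr^2)

  mono <- ssg <= .Machine$double.eps * n
  if (any(mono)) {
    warning("zero-variance SNP(s) set to p = 1: ",
            paste(colnames(genotypes)[mono], collapse = ", "))
  }
  const_y <- ssy <= .Machine$double.eps * n

  num <- crossprod(gr, yr)                       # S x V
  denom <- sqrt(outer(ssg, ssy))
  r <- num / denom
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  tsq <- df * r^2 / (1 - r^2)                    # Inf at |r| = 1 -> p = 0
  p <- stats::pf(tsq, 1, df, lower.tail = FALSE) # == 2 * pt(-|t|, df)
  p[mono, ] <- 1
  p[, const_y] <- 1
  dimnames(p) <- list(colnames(genotypes), colnames(phenotypes))
  p
}
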