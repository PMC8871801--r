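test_that("HWE chi-square matches the closed form on hand-computed counts", {
  r <- hwe_test(25, 50, 25)
  expect_equal(r$chisq, 0)
  expect_equal(r$p_hw, 1)

  # (50, 0, 50): allele freq 0.5, expected (25, 50, 25) at n = 100
  r2 <- hwe_test(50, 0, 50)
  expect_equal(r2$chisq, 100)
  expect_lt(r2$p_hw, 1e-6)

  # independent oracle: stats::chisq.test against the HWE expectation
  cnt <- c(30, 45, 25)
  q <- (2 * cnt[3] + cnt[2]) / (2 * sum(cnt))
  ora <- suppressWarnings(
    stats::chisq.test(cnt, p = c((1 - q)^2, 2 * q * (1 - q), q^2))
  )
  expect_equal(hwe_test(cnt[1], cnt[2], cnt[3])$chisq,
               unname(ora$statistic), tolerance = 1e-12)
})

test_that("HWE filter keeps equilibrium SNPs and drops gross violations", {
  g <- simulate_genotypes(800, rep(0.3, 1000), seed = 8)
  res <- hwe_filter(g, threshold = 1e-6)
  expect_gte(length(res$kept), 999)   # type-I error ~ 1e-6 per SNP
  # graft a heterozygote-free SNP: must be removed
  bad <- sample(c(0L, 2L), 800, replace = TRUE)
  g2 <- cbind(g[, 1:5], bad = bad)
  res2 <- hwe_filter(g2, threshold = 1e-6)
  expect_false("bad" %in% res2$kept)
  expect_error(hwe_filter(g, threshold = 0), "threshold")
})

test_that("p-values match the closed-form simple regression to 1e-10", {
  set.seed(101)
  n <- 60
  g <- matrix(sample(0:2, n, replace = TRUE, prob = c(.49, .42, .09)),
              dimnames = list(NULL, "s1"))
  y <- matrix(0.3 * g[, 1] + rnorm(n), dimnames = list(NULL, "v1"))
  p <- run_vgwas(g, y)
  # oracle: closed-form simple-regression t-test
  r <- cor(g[, 1], y[, 1])
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p_oracle <- 2 * pt(-abs(tstat), n - 2)
  expect_equal(p[1, 1], p_oracle, tolerance = 1e-10)
  expect_equal(p_oracle, summary(lm(y ~ g))$coefficients[2, 4], tolerance = 1e-10)
})

test_that("covariate-adjusted p-values equal the full OLS fit per pair", {
  set.seed(102)
  n <- 80
  g <- matrix(sample(0:2, n * 3, replace = TRUE), ncol = 3,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  x <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(NULL, c("c1", "c2")))
  y <- matrix(rnorm(n * 2) + 0.4 * g[, 1], ncol = 2,
              dimnames = list(NULL, c("v1", "v2")))
  p <- run_vgwas(g, y, x)
  for (j in 1:3) {
    for (v in 1:2) {
      fit <- summary(lm(y[, v] ~ g[, j] + x))$coefficients
      expect_equal(p[j, v], fit[2, 4], tolerance = 1e-10)
    }
  }
})

test_that("perfect fit yields numerically-zero p", {
  g <- matrix(rep(0:2, each = 10), dimnames = list(NULL, "s1"))
  y <- matrix(as.numeric(g), dimnames = list(NULL, "v1"))
  p <- run_vgwas(g, y)
  expect_lt(p[1, 1], 1e-12)
})

test_that("monomorphic SNPs give p = 1 with a warning", {
  set.seed(103)
  g <- cbind(s1 = rep(1L, 40), s2 = sample(0:2, 40, replace = TRUE))
  y <- matrix(rnorm(80), ncol = 2, dimnames = list(NULL, c("v1", "v2")))
  expect_warning(p <- run_vgwas(g, y), "zero-variance")
  expect_true(all(p["s1", ] == 1))
  expect_true(all(p["s2", ] > 0 & p["s2", ] <= 1))
})

test_that("rank-deficient covariates are rejected", {
  set.seed(104)
  n <- 30
  g <- matrix(sample(0:2, n, replace = TRUE), dimnames = list(NULL, "s1"))
  y <- matrix(rnorm(n), dimnames = list(NULL, "v1"))
  x <- cbind(a = rnorm(n))
  x <- cbind(x, b = 2 * x[, 1])
  expect_error(run_vgwas(g, y, x), "rank deficient")
})

test_that("output is invariant to consistent subject permutation", {
  set.seed(105)
  n <- 100
  g <- matrix(sample(0:2, n * 4, replace = TRUE), ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  x <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(NULL, c("c1", "c2")))
  y <- matrix(rnorm(n * 5), ncol = 5, dimnames = list(NULL, paste0("v", 1:5)))
  p1 <- run_vgwas(g, y, x)
  perm <- sample(n)
  p2 <- run_vgwas(g[perm, , drop = FALSE], y[perm, , drop = FALSE],
                  x[perm, , drop = FALSE])
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("a covariate orthogonal to genotype and phenotype barely moves p", {
  # the estimate and residual sum of squares are unchanged exactly; only the
  # error degrees of freedom drop by one, an O(1/n) perturbation of p
  set.seed(106)
  n <- 1000
  g <- matrix(sample(0:2, n * 3, replace = TRUE), ncol = 3,
              dimnames = list(NULL, paste0("s", 1:3)))
  y <- matrix(rnorm(n * 3), ncol = 3, dimnames = list(NULL, paste0("v", 1:3)))
  z <- qr.resid(qr(cbind(1, g, y)), rnorm(n))
  p0 <- run_vgwas(g, y)
  p1 <- run_vgwas(g, y, cbind(z = z))
  expect_lt(max(abs(p0 - p1)), 1e-2)
})

test_that("null p-values are uniform (KS at 1e4 pairs)", {
  g <- simulate_genotypes(200, rep(0.3, 50), seed = 71)
  y <- simulate_phenotypes(g, 200, blocks = list(), noise_sd = 1, seed = 71)
  p <- run_vgwas(g, y)
  expect_equal(length(p), 10000)
  ks <- suppressWarnings(stats::ks.test(as.vector(p), "punif"))
  expect_gt(ks$p.value, 0.001)
  frac <- mean(p <= 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(p)))
})
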