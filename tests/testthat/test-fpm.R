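test_that("toy database at s = 0.6 yields the six known frequent itemsets", {
  td <- toy_td()
  expected <- c("a@4", "b@4", "c@4", "a;b@3", "a;c@3", "b;c@3")
  for (mine in list(fp_growth, eclat, apriori_oracle)) {
    res <- mine(td, 0.6)
    expect_setequal(result_key(res), expected)
    expect_false("a;b;c" %in% res$items)   # support 2/5 < 0.6
  }
  cb <- count_by_size(fp_growth(td, 0.6))
  expect_equal(cb, data.frame(k = c(1L, 2L), count = c(3L, 3L)))
})

test_that("single-transaction database at s = 1 enumerates the full power set", {
  p <- matrix(c(0.01, 0.01), nrow = 2, dimnames = list(c("a", "b"), "v1"))
  td <- build_transactions(p, 0.05)
  for (mine in list(fp_growth, eclat, apriori_oracle)) {
    res <- mine(td, 1.0)
    expect_setequal(res$items, c("a", "b", "a;b"))
    expect_true(all(res$support_rate == 1))
  }
})

test_that("vacuous cases: empty DB, unreachable s, out-of-range s", {
  td_none <- build_transactions(toy_pvals(), alpha = 0.001)  # all empty
  expect_equal(nrow(fp_growth(td_none, 0.5)), 0)
  expect_equal(nrow(eclat(td_none, 0.5)), 0)
  expect_equal(nrow(apriori_oracle(td_none, 0.5)), 0)
  td <- toy_td()
  # just above the maximal singleton support rate (4/5)
  expect_equal(nrow(eclat(td, 0.81)), 0)
  expect_error(fp_growth(td, 0), "s must lie")
  expect_error(eclat(td, 1.2), "s must lie")
})

test_that("minimal threshold s = 1/TD_num returns every occurring itemset", {
  td <- toy_td()
  res <- eclat(td, 1 / td$td_num)
  ora <- enumerate_fis(td, 1 / td$td_num)
  expect_setequal(result_key(res), ora)
  # {a,b,c} occurs in 2 transactions and must now appear
  expect_true("a;b;c" %in% res$items)
})

test_that("disjoint tidsets never produce a joint itemset", {
  p <- matrix(c(0.01, 0.9, 0.9, 0.01), nrow = 2,
              dimnames = list(c("a", "b"), c("v1", "v2")))
  td <- build_transactions(p, 0.05)
  res <- eclat(td, 0.4)
  expect_setequal(res$items, c("a", "b"))
})

test_that("all three miners agree with the exhaustive enumerator", {
  for (seed in 1:12) {
    td <- random_td(seed, max_items = 8, max_trans = 25)
    set.seed(seed)
    s <- sample(seq(0.1, 0.9, 0.1), 1)
    ora <- enumerate_fis(td, s)
    expect_identical(result_key(fp_growth(td, s)), ora)
    expect_identical(result_key(eclat(td, s)), ora)
    expect_identical(result_key(apriori_oracle(td, s)), ora)
  }
})

test_that("reported supports match independent recomputation per itemset", {
  td <- random_td(99, max_items = 10, max_trans = 40)
  res <- fp_growth(td, 0.2)
  sets <- mined_itemsets(res)
  for (i in seq_along(sets)) {
    expect_identical(res$support[i], support(td, sets[[i]]))
    expect_gte(res$support_rate[i], attr(res, "s"))
  }
})

test_that("mining results are deterministically ordered", {
  td <- random_td(7)
  r1 <- fp_growth(td, 0.3)
  r2 <- fp_growth(td, 0.3)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(!is.unsorted(r1$k))
  for (k in unique(r1$k)) {
    sub <- r1[r1$k == k, ]
    expect_true(all(diff(sub$support_rate) <= 0))
  }
})

test_that("count_by_size tracks the result and the s-sweep is monotone", {
  td <- random_td(13)
  grid <- seq(0.1, 0.9, 0.2)
  totals <- integer(0)
  ones <- integer(0)
  for (s in grid) {
    fpg <- fp_growth(td, s)
    ecl <- eclat(td, s)
    cb <- count_by_size(fpg)
    expect_equal(sum(cb$count), nrow(fpg))
    totals <- c(totals, nrow(fpg))
    # 1-item counts coincide across algorithms at equal s
    ones <- c(ones, sum(fpg$k == 1))
    expect_equal(sum(fpg$k == 1), sum(ecl$k == 1))
  }
  expect_true(all(diff(totals) <= 0))
  expect_equal(count_by_size(fp_growth(td, 0.999)),
               data.frame(k = integer(0), count = integer(0)))
})

test_that("apriori oracle warns on oversized item universes", {
  td <- random_td(3, max_items = 15, max_trans = 20)
  expect_warning(apriori_oracle(td, 1 / td$td_num, max_items = 2), "guard")
})

test_that("mining result TSV export is self-describing and re-readable", {
  td <- toy_td()
  res <- eclat(td, 0.6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mining_result(res, f)
  lines <- readLines(f)
  expect_match(lines[1], "algorithm: eclat")
  back <- utils::read.table(f, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(back$items, res$items)
  expect_equal(back$support, res$support)
})
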