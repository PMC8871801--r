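test_that("confidence is the exact ratio with validated inputs", {
  expect_equal(confidence(0.74, 0.82), 0.74 / 0.82)
  expect_equal(confidence(0.5, 0.5), 1.0)
  expect_equal(confidence(3, 4), 0.75)          # counts work too
  expect_error(confidence(0.1, 0), "positive")
  expect_error(confidence(0.9, 0.8), "inconsistent")
})

test_that("display rounding is half-up to two decimals with '--' flagging", {
  expect_equal(format_confidence(0.905), "0.91")   # half rounds up
  expect_equal(format_confidence(0.67 / 0.68), "0.99")
  expect_equal(format_confidence(c(0.69, 0.85), min_confidence = 0.7),
               c("--", "0.85"))
})

test_that("rules from 2-itemsets have the textbook confidences", {
  # a in 8, b in 9, both in 7 of 10 transactions
  member <- rbind(a = c(rep(1, 8), 0, 0), b = c(rep(1, 7), 0, 1, 1))
  p <- ifelse(member == 1, 0.01, 0.5)
  dimnames(p) <- list(c("a", "b"), sprintf("v%02d", 1:10))
  td <- build_transactions(p, 0.05)
  res <- eclat(td, 0.5)
  rules <- generate_rules(res, td, min_confidence = 0.8)
  ab <- rules[rules$antecedent == "a", ]
  ba <- rules[rules$antecedent == "b", ]
  expect_equal(ab$confidence, 7 / 8)
  expect_equal(ba$confidence, 7 / 9)
  expect_true(ab$meets_min_confidence)
  expect_false(ba$meets_min_confidence)
  expect_equal(ba$display, "--")   # flagged, not dropped
})

test_that("a universal consequent always yields confidence 1", {
  member <- rbind(a = c(1, 1, 0, 1, 0, 1), b = rep(1, 6))
  p <- ifelse(member == 1, 0.01, 0.5)
  dimnames(p) <- list(c("a", "b"), paste0("v", 1:6))
  td <- build_transactions(p, 0.05)
  rules <- generate_rules(eclat(td, 0.5), td)
  expect_equal(rules$confidence[rules$antecedent == "a" & rules$consequent == "b"], 1)
})

test_that("rule invariants hold on random databases", {
  for (seed in c(4, 9, 17)) {
    td <- random_td(seed, max_items = 8, max_trans = 30)
    res <- eclat(td, 0.2)
    rules <- generate_rules(res, td, min_confidence = 0.7)
    if (!nrow(rules)) next
    # confidence * support(A) = support(A u B), exactly on counts
    expect_equal(rules$confidence * rules$support_a, rules$support_ab,
                 tolerance = 1e-12)
    # confidence >= support rate of the union
    expect_true(all(rules$confidence >= rules$support_ab - 1e-12))
    # bidirectional 1 -> 1 pairs: conf(A->B)/conf(B->A) = support(B)/support(A)
    two <- rules[rules$k == 2, ]
    for (i in seq_len(nrow(two))) {
      rev <- two[two$antecedent == two$consequent[i] &
                 two$consequent == two$antecedent[i], ]
      expect_equal(two$confidence[i] / rev$confidence,
                   rev$support_a / two$support_a[i], tolerance = 1e-12)
    }
  }
})

test_that("itemsets absent from the supplied TD are rejected", {
  td1 <- toy_td()
  res <- eclat(td1, 0.6)
  p <- matrix(0.5, 3, 5, dimnames = list(c("a", "b", "c"), paste0("w", 1:5)))
  td_empty <- build_transactions(p, 0.05)
  expect_error(generate_rules(res, td_empty), "not frequent")
})

test_that("the prefix rule chain reproduces planted high/low confidences", {
  # five items where e is rare: chain confidences high until the last step
  member <- rbind(
    a = rep(1, 10),
    b = c(rep(1, 9), 0),
    c = c(rep(1, 8), 0, 0),
    d = c(rep(1, 8), 0, 0),
    e = c(rep(1, 4), rep(0, 6))
  )
  p <- ifelse(member == 1, 0.01, 0.5)
  dimnames(p) <- list(rownames(member), sprintf("v%02d", 1:10))
  td <- build_transactions(p, 0.05)
  ch <- rule_chain(td, c("a", "b", "c", "d", "e"), min_confidence = 0.7)
  expect_equal(nrow(ch), 4)
  expect_true(all(ch$confidence[1:3] >= 0.8))
  expect_lt(ch$confidence[4], 0.7)
  expect_equal(ch$display[4], "--")
  expect_equal(ch$confidence, ch$support_ab / ch$support_a, tolerance = 1e-12)
})

test_that("the full-power-set policy emits every proper antecedent", {
  td <- toy_td()
  res <- eclat(td, 1 / td$td_num)   # includes {a,b,c}
  rules <- generate_rules(res, td, policy = "all")
  abc <- rules[rules$k == 3, ]
  expect_equal(nrow(abc), 6)   # 3 singleton + 3 pair antecedents
})
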