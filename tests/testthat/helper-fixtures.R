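# Shared fixtures: all generated in code, nothing on disk.

# Random transaction database built through the real constructor: a uniform
# p-value matrix thresholded at a random alpha gives transactions of varied
# density.
random_td <- function(seed, max_items = 15, max_trans = 60) {
  set.seed(seed)
  n_items <- sample(4:max_items, 1)
  n_trans <- sample(10:max_trans, 1)
  alpha <- stats::runif(1, 0.3, 0.6)
  p <- matrix(stats::runif(n_items * n_trans), nrow = n_items,
              dimnames = list(sprintf("i%02d", seq_len(n_items)),
                              sprintf("v%03d", seq_len(n_trans))))
  build_transactions(p, alpha)
}

# Canonical serialization of a mining result for set comparisons.
result_key <- function(res) {
  sort(paste(res$items, res$support, sep = "@"))
}

# Independent brute-force enumerator: scans every nonempty subset of the item
# universe and counts its support by direct transaction scan. Shares no code
# with fp_growth / eclat / apriori_oracle beyond the transaction_db fields.
enumerate_fis <- function(td, s) {
  items <- sort(td$items)
  out <- character(0)
  for (k in seq_along(items)) {
    for (set in utils::combn(items, k, simplify = FALSE)) {
      sup <- sum(vapply(td$transactions, function(tr) all(set %in% tr), logical(1)))
      if (sup / td$td_num >= s) {
        out <- c(out, paste(paste(set, collapse = ";"), sup, sep = "@"))
      }
    }
  }
  sort(out)
}

# The five-transaction toy database {abc, ab, ac, bc, abc}.
toy_td <- function() {
  member <- rbind(
    a = c(1, 1, 1, 0, 1),
    b = c(1, 1, 0, 1, 1),
    c = c(1, 0, 1, 1, 1)
  )
  p <- ifelse(member == 1, 0.01, 0.5)
  dimnames(p) <- list(c("a", "b", "c"), sprintf("T%d", 1:5))
  build_transactions(p, 0.05)
}

# Hand-checkable 3 SNP x 4 voxel p-value matrix.
toy_pvals <- function() {
  p <- rbind(
    s1 = c(0.01, 0.2, 0.05, 0.9),
    s2 = c(0.04, 0.03, 0.6, 0.01),
    s3 = c(0.5, 0.5, 0.5, 0.5)
  )
  colnames(p) <- paste0("v", 1:4)
  p
}
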