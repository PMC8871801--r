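#' Confidence of an association rule
#'
#' `confidence(A -> B) = support(A and B) / support(A)`: the conditional
#' frequency, among transactions containing the antecedent, of also
#' containing the consequent. Inputs may be counts or rates, as long as both
#' are on the same scale.
#'
#' @param support_ab Support of the combined itemset (A together with B).
#' @param support_a Support of the antecedent A; must be positive and at
#'   least `support_ab`.
#' @return The exact ratio, in \[0, 1\]. Display rounding is a separate
#'   concern: see [format_confidence()].
#' @export
confidence <- function(support_ab, support_a) {
  stopifnot(is.numeric(support_ab), is.numeric(support_a))
  if (any(support_a <= 0)) stop("support_a must be positive (rule undefined)")
  if (any(support_ab < 0)) stop("support_ab must be non-negative")
  if (any(support_ab > support_a)) {
    stop("inconsistent inputs: support_ab exceeds support_a")
  }
  support_ab / support_a
}

#' Format a confidence for reporting
#'
#' Half-up rounding to `digits` decimals (the convention used in the
#' published rule tables); values below `min_confidence` are shown as "--"
#' rather than dropped, mirroring how weak rules are flagged in print.
#'
#' @param conf Numeric confidences.
#' @param min_confidence Rules below this display as "--" (`NULL` disables).
#' @param digits Decimal places.
#' @return Character vector.
#' @export
format_confidence <- function(conf, min_confidence = NULL, digits = 2) {
  out <- sprintf(paste0("%.", digits, "f"), round_half_up(conf, digits))
  if (!is.null(min_confidence)) out[conf < min_confidence] <- "--"
  out
}

#' Generate association rules from mined frequent itemsets
#'
#' For every frequent itemset of size >= 2, emits rules whose supports are
#' recomputed on the transaction database (never trusted from the mining
#' result). The default policy emits every (k-1)-item antecedent -> 1-item
#' consequent rule, which for 2-itemsets is exactly the pair of
#' single-item -> single-item rules; `policy = "all"` enumerates every
#' nonempty proper subset as antecedent (exponential, for small itemsets
#' only). Rules below `min_confidence` are flagged via
#' `meets_min_confidence` and display as "--", not silently dropped.
#'
#' @param result A `mining_result`.
#' @param td The `transaction_db` the result was mined from.
#' @param min_confidence Flagging threshold in \[0, 1\].
#' @param policy "k_minus_1" (default) or "all".
#' @return Data frame: `antecedent`, `consequent` (";"-joined ids),
#'   `support_a`, `support_ab` (rates), `confidence` (full precision),
#'   `meets_min_confidence`, `display` (2 dp, "--" when below threshold),
#'   plus the mining `s` as an attribute. Sorted by (k, descending
#'   confidence, antecedent, consequent).
#' @export
generate_rules <- function(result, td, min_confidence = 0.8,
                           policy = c("k_minus_1", "all")) {
  stopifnot(inherits(result, "mining_result"), inherits(td, "transaction_db"),
            min_confidence >= 0, min_confidence <= 1)
  policy <- match.arg(policy)
  s <- attr(result, "s")
  min_count <- min_support_count(s, td$td_num)
  itemsets <- mined_itemsets(result)
  rows <- list()
  sup_cache <- new.env(parent = emptyenv())
  sup <- function(its) {
    key <- paste(its, collapse = ";")
    val <- get0(key, envir = sup_cache)
    if (is.null(val)) {
      val <- support(td, its)
      assign(key, val, envir = sup_cache)
    }
    val
  }
  for (fi in itemsets) {
    k <- length(fi)
    if (k < 2L) next
    sup_fi <- sup(fi)
    if (sup_fi < min_count) {
      stop("itemset {", paste(fi, collapse = ", "),
           "} is not frequent in the supplied transaction database")
    }
    antecedents <- if (policy == "k_minus_1") {
      lapply(seq_len(k), function(d) fi[-d])
    } else {
      unlist(lapply(seq_len(k - 1L), function(m) {
        asplit(utils::combn(fi, m), 2)
      }), recursive = FALSE)
    }
    for (a in antecedents) {
      b <- setdiff(fi, a)
      sup_a <- sup(a)
      rows[[length(rows) + 1L]] <- data.frame(
        antecedent = paste(a, collapse = ";"),
        consequent = paste(b, collapse = ";"),
        k = k,
        support_a = sup_a / td$td_num,
        support_ab = sup_fi / td$td_num,
        confidence = confidence(sup_fi, sup_a)
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(antecedent = character(0), consequent = character(0),
               k = integer(0), support_a = numeric(0), support_ab = numeric(0),
               confidence = numeric(0))
  }
  out <- out[!duplicated(out[c("antecedent", "consequent")]), ]
  out$meets_min_confidence <- out$confidence >= min_confidence
  out$display <- format_confidence(out$confidence, min_confidence)
  out <- out[order(out$k, -out$confidence, out$antecedent, out$consequent), ]
  rownames(out) <- NULL
  attr(out, "s") <- s
  attr(out, "min_confidence") <- min_confidence
  out
}

#' Confidence chain along an ordered itemset
#'
#' For an ordered item vector (a1, ..., aK), computes the rule
#' (a1, ..., a_{k-1}) -> a_k for k = 2..K, with supports taken from the
#' transaction database. This is the "grow the itemset one SNP at a time"
#' reading of a k-item frequent itemset.
#'
#' @param td A `transaction_db`.
#' @param items Ordered character vector of item ids (length >= 2).
#' @param min_confidence Flagging threshold for the display column.
#' @return Data frame: `antecedent`, `consequent`, `support_a`, `support_ab`,
#'   `confidence`, `display`.
#' @export
rule_chain <- function(td, items, min_confidence = 0.8) {
  stopifnot(inherits(td, "transaction_db"), length(items) >= 2L)
  check_items(td, items)
  rows <- lapply(2:length(items), function(k) {
    a <- items[seq_len(k - 1L)]
    ab <- items[seq_len(k)]
    sup_a <- support(td, a)
    sup_ab <- support(td, ab)
    data.frame(antecedent = paste(a, collapse = ";"),
               consequent = items[k],
               support_a = sup_a / td$td_num,
               support_ab = sup_ab / td$td_num,
               confidence = if (sup_a > 0) sup_ab / sup_a else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$display <- format_confidence(out$confidence, min_confidence)
  out
}
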