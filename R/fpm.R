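#' @name fpm
#' @title Frequent itemset mining of the transactional database
#'
#' @description
#' Two mining algorithms over a `transaction_db` plus a brute-force oracle:
#' `fp_growth()` (compressed prefix tree with per-item pointer chains and
#' recursive conditional trees), `eclat()` (vertical transaction-id sets and
#' recursive intersection), and `apriori_oracle()` (level-wise candidate
#' generation, intended as ground truth on small databases). All three return
#' the identical collection of itemsets whose support rate meets the
#' threshold `s`.
#'
#' The keep predicate is `support / td_num >= s`. It is evaluated once as the
#' minimal integer count satisfying it, and that integer bound is used
#' throughout a mining run, so the rate-vs-count comparison cannot drift at
#' representable boundaries.
NULL

td_checksum <- function(td) {
  sizes <- lengths(td$transactions)
  item_h <- vapply(td$items, function(it) sum(utf8ToInt(it)), numeric(1))
  per_tr <- vapply(td$transactions, function(tr) {
    if (!length(tr)) 0 else sum(item_h[match(tr, td$items)])
  }, numeric(1))
  sum((per_tr + sizes * 131) * seq_along(per_tr)) %% 2147483647
}

new_mining_result <- function(itemsets, supports, algorithm, s, td) {
  k <- lengths(itemsets)
  items <- vapply(itemsets, function(x) paste(sort(x), collapse = ";"), character(1))
  df <- data.frame(items = items, k = as.integer(k),
                   support = as.integer(supports),
                   support_rate = as.integer(supports) / td$td_num)
  if (anyDuplicated(df$items)) stop("internal error: duplicate itemsets emitted")
  df <- df[order(df$k, -df$support_rate, df$items), ]
  rownames(df) <- NULL
  structure(df, class = c("mining_result", "data.frame"),
            algorithm = algorithm, s = s, td_num = td$td_num,
            td_checksum = td_checksum(td))
}

#' @export
print.mining_result <- function(x, ...) {
  cat("mining_result (", attr(x, "algorithm"), "): ", nrow(x),
      " frequent itemsets at s = ", attr(x, "s"),
      " over ", attr(x, "td_num"), " transactions\n", sep = "")
  NextMethod()
}

#' Extract mined itemsets as a list of character vectors
#'
#' @param result A `mining_result`.
#' @return List of sorted character vectors, one per frequent itemset.
#' @export
mined_itemsets <- function(result) {
  strsplit(result$items, ";", fixed = TRUE)
}

check_s <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0 || s > 1) {
    stop("support rate threshold s must lie in (0, 1]")
  }
  invisible(s)
}

item_counts <- function(td) {
  tab <- table(factor(unlist(td$transactions, use.names = FALSE), levels = td$items))
  stats::setNames(as.integer(tab), td$items)
}

# Descending count, ties broken by item id, as the canonical insertion order.
order_items <- function(counts) {
  names(counts)[order(-counts, names(counts))]
}

## ---- FP-tree -------------------------------------------------------------

new_fp_node <- function(item, parent) {
  e <- new.env(parent = emptyenv())
  e$item <- item
  e$count <- 0L
  e$parent <- parent
  e$children <- list()
  e$nxt <- NULL   # next node in this item's header chain
  e
}

# weighted_transactions: list of list(items = ordered char vec, count = int)
build_fp_tree <- function(weighted_transactions) {
  root <- new_fp_node(NA_character_, NULL)
  header <- new.env(parent = emptyenv())  # item -> chain head
  for (wt in weighted_transactions) {
    node <- root
    for (it in wt$items) {
      child <- node$children[[it]]
      if (is.null(child)) {
        child <- new_fp_node(it, node)
        node$children[[it]] <- child
        child$nxt <- get0(it, envir = header)
        assign(it, child, envir = header)
      }
      child$count <- child$count + wt$count
      node <- child
    }
  }
  list(root = root, header = header)
}

chain_nodes <- function(header, item) {
  out <- list()
  node <- get0(item, envir = header)
  while (!is.null(node)) {
    out[[length(out) + 1L]] <- node
    node <- node$nxt
  }
  out
}

# Root-to-leaf check: TRUE iff the tree is a single path; returns the path.
fp_single_path <- function(root) {
  path <- list()
  node <- root
  repeat {
    kids <- node$children
    if (length(kids) == 0L) return(list(single = TRUE, path = path))
    if (length(kids) > 1L) return(list(single = FALSE, path = NULL))
    node <- kids[[1L]]
    path[[length(path) + 1L]] <- node
  }
}

fp_growth_mine <- function(tree, item_order, suffix, min_count, emit) {
  sp <- fp_single_path(tree$root)
  if (sp$single) {
    np <- length(sp$path)
    if (np == 0L) return(invisible())
    if (np <= 20L) {
      # enumerate every subset of the path; support of a subset is the count
      # of its deepest node (counts are non-increasing down a path)
      items <- vapply(sp$path, function(nd) nd$item, character(1))
      counts <- vapply(sp$path, function(nd) nd$count, integer(1))
      for (mask in seq_len(2^np - 1L)) {
        sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(np - 1L))) != 0L)
        emit(c(items[sel], suffix), counts[max(sel)])
      }
      return(invisible())
    }
    # fall through to the general branch for unusually long single paths
  }
  for (it in rev(item_order)) {             # ascending frequency
    nodes <- chain_nodes(tree$header, it)
    sup_it <- sum(vapply(nodes, function(nd) nd$count, integer(1)))
    emit(c(it, suffix), sup_it)
    # conditional pattern base: prefix path of every node in the chain
    base <- list()
    for (nd in nodes) {
      pref <- character(0)
      p <- nd$parent
      while (!is.null(p) && !is.na(p$item)) {
        pref <- c(p$item, pref)
        p <- p$parent
      }
      if (length(pref)) base[[length(base) + 1L]] <- list(items = pref, count = nd$count)
    }
    if (!length(base)) next
    # conditional item counts and order
    ccnt <- integer(0)
    for (b in base) {
      for (bi in b$items) ccnt[bi] <- (if (is.na(ccnt[bi])) 0L else ccnt[bi]) + b$count
    }
    keep <- names(ccnt)[ccnt >= min_count]
    if (!length(keep)) next
    corder <- keep[order(-ccnt[keep], keep)]
    cond <- lapply(base, function(b) {
      its <- b$items[b$items %in% keep]
      if (!length(its)) return(NULL)
      list(items = its[order(match(its, corder))], count = b$count)
    })
    cond <- cond[!vapply(cond, is.null, logical(1))]
    if (!length(cond)) next
    fp_growth_mine(build_fp_tree(cond), corder, c(it, suffix), min_count, emit)
  }
}

#' Mine frequent itemsets with FP-Growth
#'
#' Builds a frequency-ordered FP-tree (items sorted by descending support,
#' ties by item id), then for each item in ascending frequency emits the item
#' joined to the current suffix, assembles the conditional pattern base from
#' the item's pointer chain, builds the conditional FP-tree and recurses
#' while it is non-empty. Trees that collapse to a single path are expanded
#' by direct subset enumeration.
#'
#' @param td A `transaction_db`.
#' @param s Minimum support rate in (0, 1].
#' @return A `mining_result`: data frame of `items` (";"-joined, sorted),
#'   `k`, `support`, `support_rate`, ordered by (k, descending support rate,
#'   items).
#' @export
fp_growth <- function(td, s) {
  stopifnot(inherits(td, "transaction_db"))
  check_s(s)
  min_count <- min_support_count(s, td$td_num)
  counts <- item_counts(td)
  freq <- names(counts)[counts >= min_count]
  acc_items <- list()
  acc_sup <- integer(0)
  emit <- function(itemset, sup) {
    acc_items[[length(acc_items) + 1L]] <<- itemset
    acc_sup[[length(acc_sup) + 1L]] <<- sup
  }
  if (length(freq)) {
    ord <- freq[order(-counts[freq], freq)]
    wtrans <- lapply(td$transactions, function(tr) {
      its <- tr[tr %in% freq]
      if (!length(its)) return(NULL)
      list(items = its[order(match(its, ord))], count = 1L)
    })
    wtrans <- wtrans[!vapply(wtrans, is.null, logical(1))]
    fp_growth_mine(build_fp_tree(wtrans), ord, character(0), min_count, emit)
  }
  new_mining_result(acc_items, acc_sup, "fpgrowth", s, td)
}

## ---- Eclat ---------------------------------------------------------------

eclat_mine <- function(prefix, cands, min_count, emit) {
  # cands: list of list(item, tids); already frequent, in canonical order
  for (i in seq_along(cands)) {
    ci <- cands[[i]]
    emit(c(prefix, ci$item), length(ci$tids))
    ext <- list()
    for (j in seq_along(cands)) {
      if (j <= i) next
      cj <- cands[[j]]
      tids <- ci$tids[ci$tids %in% cj$tids]
      if (length(tids) >= min_count) {
        ext[[length(ext) + 1L]] <- list(item = cj$item, tids = tids)
      }
    }
    if (length(ext)) eclat_mine(c(prefix, ci$item), ext, min_count, emit)
  }
}

#' Mine frequent itemsets with Eclat
#'
#' Converts the database to vertical form (each item carries the set of
#' transaction ids containing it), then recursively intersects tid-sets
#' within each equivalence class: the tid-set of an extended itemset is the
#' intersection of its parts, and its support is the intersection's size.
#' Returns the same itemset collection as [fp_growth()].
#'
#' @inheritParams fp_growth
#' @return A `mining_result`.
#' @export
eclat <- function(td, s) {
  stopifnot(inherits(td, "transaction_db"))
  check_s(s)
  min_count <- min_support_count(s, td$td_num)
  counts <- item_counts(td)
  freq <- names(counts)[counts >= min_count]
  acc_items <- list()
  acc_sup <- integer(0)
  emit <- function(itemset, sup) {
    acc_items[[length(acc_items) + 1L]] <<- itemset
    acc_sup[[length(acc_sup) + 1L]] <<- sup
  }
  if (length(freq)) {
    ord <- freq[order(-counts[freq], freq)]
    tidsets <- lapply(ord, function(it) {
      list(item = it,
           tids = which(vapply(td$transactions, function(tr) it %in% tr, logical(1))))
    })
    eclat_mine(character(0), tidsets, min_count, emit)
  }
  new_mining_result(acc_items, acc_sup, "eclat", s, td)
}

## ---- Apriori oracle ------------------------------------------------------

#' Brute-force Apriori miner (test oracle)
#'
#' Level-wise candidate generation with downward-closure pruning and direct
#' support counting by database scan. Intended as ground truth for
#' equivalence tests on small databases; warns when the frequent-item
#' universe exceeds `max_items` (combinatorial blow-up).
#'
#' @inheritParams fp_growth
#' @param max_items Guard on the number of distinct frequent items.
#' @return A `mining_result`.
#' @export
apriori_oracle <- function(td, s, max_items = 20L) {
  stopifnot(inherits(td, "transaction_db"))
  check_s(s)
  min_count <- min_support_count(s, td$td_num)
  counts <- item_counts(td)
  freq1 <- sort(names(counts)[counts >= min_count])
  if (length(freq1) > max_items) {
    warning("apriori_oracle: ", length(freq1), " frequent items exceeds guard of ",
            max_items, "; expect combinatorial cost")
  }
  acc_items <- list()
  acc_sup <- integer(0)
  count_sup <- function(itemset) {
    sum(vapply(td$transactions, function(tr) all(itemset %in% tr), logical(1)))
  }
  level <- lapply(freq1, identity)   # list of sorted char vectors
  for (it in freq1) {
    acc_items[[length(acc_items) + 1L]] <- it
    acc_sup[[length(acc_sup) + 1L]] <- counts[[it]]
  }
  k <- 1L
  while (length(level)) {
    keys <- vapply(level, paste, character(1), collapse = ";")
    # join step: pairs sharing their first k-1 items
    nxt <- list()
    if (length(level) >= 2L) {
      prefixes <- vapply(level, function(x) paste(x[-length(x)], collapse = ";"),
                         character(1))
      for (grp in split(seq_along(level), prefixes)) {
        if (length(grp) < 2L) next
        for (a in seq_along(grp)) {
          for (b in seq_along(grp)) {
            if (b <= a) next
            cand <- sort(union(level[[grp[a]]], level[[grp[b]]]))
            # prune: every k-subset must be frequent
            subs <- vapply(seq_along(cand), function(d) {
              paste(cand[-d], collapse = ";")
            }, character(1))
            if (all(subs %in% keys)) nxt[[length(nxt) + 1L]] <- cand
          }
        }
      }
    }
    nxt <- unique(nxt)
    level <- list()
    for (cand in nxt) {
      sup <- count_sup(cand)
      if (sup >= min_count) {
        level[[length(level) + 1L]] <- cand
        acc_items[[length(acc_items) + 1L]] <- cand
        acc_sup[[length(acc_sup) + 1L]] <- sup
      }
    }
    k <- k + 1L
  }
  new_mining_result(acc_items, acc_sup, "apriori", s, td)
}

#' Count mined itemsets by size
#'
#' @param result A `mining_result`.
#' @return Data frame with columns `k` and `count` (absent sizes omitted;
#'   an empty result yields zero rows).
#' @export
count_by_size <- function(result) {
  stopifnot(inherits(result, "mining_result"))
  if (!nrow(result)) return(data.frame(k = integer(0), count = integer(0)))
  tab <- table(result$k)
  data.frame(k = as.integer(names(tab)), count = as.integer(tab))
}
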