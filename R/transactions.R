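#' Build the transactional database from a p-value matrix
#'
#' Each voxel becomes one transaction; the items of a transaction are the
#' SNPs significant there, i.e. with p <= alpha (inclusive, so boundary
#' p-values count as significant). Voxels with no significant SNP yield empty
#' transactions, which are retained: they still count in the denominator
#' `td_num`, so support rates are fractions of *all* voxels considered.
#'
#' @param pvals SNPs x voxels numeric matrix of p-values with dimnames.
#' @param alpha Significance threshold in (0, 1).
#' @param voxel_subset Optional character vector of voxel ids to restrict to
#'   (order preserved as in the matrix). Default: all voxels.
#' @return An object of class `transaction_db`: list with `transactions`
#'   (named list of sorted item character vectors), `voxel_ids`, `items`
#'   (the SNP universe), `td_num`, `alpha`.
#' @export
build_transactions <- function(pvals, alpha = 0.05, voxel_subset = NULL) {
  stopifnot(is.matrix(pvals), alpha > 0, alpha < 1)
  if (is.null(rownames(pvals)) || is.null(colnames(pvals))) {
    stop("pvals must carry SNP rownames and voxel colnames")
  }
  if (!is.null(voxel_subset)) {
    if (length(voxel_subset) == 0L) stop("voxel_subset must be non-empty")
    missing <- setdiff(voxel_subset, colnames(pvals))
    if (length(missing)) stop("unknown voxel id(s): ", paste(missing, collapse = ", "))
    pvals <- pvals[, colnames(pvals) %in% voxel_subset, drop = FALSE]
  }
  snps <- rownames(pvals)
  trans <- lapply(seq_len(ncol(pvals)), function(v) {
    sort(snps[pvals[, v] <= alpha])
  })
  names(trans) <- colnames(pvals)
  structure(
    list(transactions = trans, voxel_ids = colnames(pvals), items = snps,
         td_num = ncol(pvals), alpha = alpha),
    class = "transaction_db"
  )
}

#' @export
print.transaction_db <- function(x, ...) {
  cat("transaction_db: ", x$td_num, " transactions (voxels), ",
      length(x$items), " items (SNPs), alpha = ", x$alpha, "\n", sep = "")
  sizes <- lengths(x$transactions)
  cat("items per transaction: min ", min(sizes), ", median ",
      stats::median(sizes), ", max ", max(sizes), "\n", sep = "")
  invisible(x)
}

check_items <- function(td, itemset) {
  if (length(itemset) == 0L) stop("itemset must be non-empty")
  unknown <- setdiff(itemset, td$items)
  if (length(unknown)) {
    stop("unknown item(s): ", paste(unknown, collapse = ", "))
  }
  invisible(itemset)
}

#' Support of an itemset
#'
#' Count of transactions containing every item of `itemset`. For a single
#' item this is the number of voxels where that SNP is significant.
#'
#' @param td A `transaction_db`.
#' @param itemset Character vector of item (SNP) ids.
#' @return Integer count in `[0, td_num]`.
#' @export
support <- function(td, itemset) {
  stopifnot(inherits(td, "transaction_db"))
  check_items(td, itemset)
  sum(vapply(td$transactions, function(tr) all(itemset %in% tr), logical(1)))
}

#' Support rate of an itemset
#'
#' `support(td, itemset) / td_num`: the fraction of all transactions (voxels)
#' containing the whole itemset.
#'
#' @inheritParams support
#' @return Numeric in \[0, 1\].
#' @export
support_rate <- function(td, itemset) {
  support(td, itemset) / td$td_num
}

#' Per-item support table
#'
#' Support and support rate of every single item, sorted by descending
#' support rate (ties broken by item id).
#'
#' @param td A `transaction_db`.
#' @return Data frame with columns `item`, `support`, `support_rate`.
#' @export
support_table <- function(td) {
  stopifnot(inherits(td, "transaction_db"))
  counts <- table(factor(unlist(td$transactions, use.names = FALSE),
                         levels = td$items))
  out <- data.frame(item = td$items, support = as.integer(counts),
                    support_rate = as.integer(counts) / td$td_num)
  out <- out[order(-out$support_rate, out$item), ]
  rownames(out) <- NULL
  out
}

#' Restrict a p-value matrix to one ROI's voxels
#'
#' Column-restricts the SNP x voxel matrix to the voxels carrying `label` in
#' the ROI map, preserving SNP rows and the matrix's voxel order.
#'
#' @param pvals SNPs x voxels p-value matrix.
#' @param roi_map Data frame with columns `voxel_id`, `label`.
#' @param label ROI label to select.
#' @return The column-restricted p-value matrix.
#' @export
subset_by_roi <- function(pvals, roi_map, label) {
  stopifnot(is.matrix(pvals), is.data.frame(roi_map))
  if (!all(c("voxel_id", "label") %in% names(roi_map))) {
    stop("roi_map must have columns voxel_id and label")
  }
  if (!label %in% roi_map$label) {
    stop("unknown ROI label '", label, "'; available: ",
         paste(sort(unique(roi_map$label)), collapse = ", "))
  }
  vox <- roi_map$voxel_id[roi_map$label == label]
  keep <- colnames(pvals) %in% vox
  if (!any(keep)) stop("ROI '", label, "' has no voxels in the p-value matrix")
  pvals[, keep, drop = FALSE]
}
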