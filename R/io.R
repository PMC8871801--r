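#' Write a named numeric matrix as TSV
#'
#' First column holds the row identifiers (header `id`), remaining columns
#' the matrix columns. Round-trips through [read_matrix_tsv()].
#'
#' @param x Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @return Matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = NA)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Export transactions in FIMI basket format
#'
#' One line per transaction, items separated by single spaces; empty
#' transactions become empty lines (they still count). Interoperable with
#' standard frequent-itemset-mining tools.
#'
#' @param td A `transaction_db`.
#' @param path Output path.
#' @export
write_basket <- function(td, path) {
  stopifnot(inherits(td, "transaction_db"))
  lines <- vapply(td$transactions, paste, character(1), collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' Read a FIMI basket file as a transaction database
#'
#' Voxel/transaction ids are synthesized positionally (`t00001`, ...); the
#' item universe is taken from the file unless supplied.
#'
#' @param path Input path.
#' @param items Optional item universe (default: all items seen).
#' @param alpha Significance threshold to record (metadata only here).
#' @return A `transaction_db`.
#' @export
read_basket <- function(path, items = NULL, alpha = 0.05) {
  lines <- readLines(path)
  trans <- lapply(strsplit(lines, " ", fixed = TRUE), function(x) sort(x[nzchar(x)]))
  ids <- sprintf("t%05d", seq_along(trans))
  names(trans) <- ids
  if (is.null(items)) items <- sort(unique(unlist(trans, use.names = FALSE)))
  structure(
    list(transactions = trans, voxel_ids = ids, items = items,
         td_num = length(trans), alpha = alpha),
    class = "transaction_db"
  )
}

#' Write / read a voxel-to-ROI map
#'
#' Two-column TSV: `voxel_id`, `label`.
#'
#' @param roi_map Data frame with columns `voxel_id`, `label`.
#' @param path File path.
#' @export
write_roi_map <- function(roi_map, path) {
  stopifnot(all(c("voxel_id", "label") %in% names(roi_map)))
  utils::write.table(roi_map[c("voxel_id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_map
#' @export
read_roi_map <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character"))
}

#' Write a mining result as TSV
#'
#' Columns: items (";"-joined), k, support, support_rate; the algorithm, s
#' and TD size are recorded in `# key: value` header comments so the file is
#' self-describing.
#'
#' @param result A `mining_result`.
#' @param path Output path.
#' @export
write_mining_result <- function(result, path) {
  stopifnot(inherits(result, "mining_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# algorithm: %s", attr(result, "algorithm")), con)
  writeLines(sprintf("# s: %.17g", attr(result, "s")), con)
  writeLines(sprintf("# td_num: %d", attr(result, "td_num")), con)
  utils::write.table(as.data.frame(result), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an association-rule table as TSV
#'
#' @param rules Data frame from [generate_rules()].
#' @param path Output path.
#' @export
write_rules_tsv <- function(rules, path) {
  utils::write.table(rules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
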