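#' Which ROIs does a SNP activate?
#'
#' Implements the top-fraction voxel criterion: within each region of
#' interest, rank the voxels by the SNP's per-voxel association strength
#' (descending), keep the top `ceiling(top_frac * n_voxels)` of them, and
#' declare the region activated iff every kept voxel is significant
#' (p <= alpha by default). The ranking score is `-log10(p)` for the SNP at
#' that voxel — the association-strength analogue of ranking voxels by how
#' strongly the SNP explains them; ties are broken by voxel id so runs are
#' deterministic.
#'
#' The ceiling keeps at least one voxel even in tiny regions. With the
#' default significance ranking the criterion is monotone: activation at a
#' given `alpha` implies activation at any larger `alpha`, and activation at
#' a given `top_frac` implies activation at any smaller one.
#'
#' @param pvals SNPs x voxels p-value matrix.
#' @param roi_map Data frame with columns `voxel_id`, `label`.
#' @param snp_id SNP (row) to assess.
#' @param top_frac Fraction of each ROI's voxels to examine, in (0, 1].
#' @param alpha Significance threshold for the kept voxels.
#' @param labels Optional subset of ROI labels (default: all in the map).
#'   Labels with no voxels in the matrix are skipped with a warning.
#' @param comparator "le" (p <= alpha, default) or "lt" (strict).
#' @return An object of class `activation_result`: a data frame with one row
#'   per ROI (`snp_id`, `roi`, `n_voxels`, `n_top`, `min_p_top`, `max_p_top`,
#'   `activated`) and an attribute `top_voxels` holding, per ROI, the ranked
#'   kept voxels and their p-values.
#' @export
activated_rois <- function(pvals, roi_map, snp_id, top_frac = 0.2,
                           alpha = 0.05, labels = NULL,
                           comparator = c("le", "lt")) {
  stopifnot(is.matrix(pvals), is.data.frame(roi_map),
            top_frac > 0, top_frac <= 1, alpha > 0, alpha < 1)
  comparator <- match.arg(comparator)
  if (!snp_id %in% rownames(pvals)) stop("unknown SNP id '", snp_id, "'")
  if (is.null(labels)) labels <- sort(unique(roi_map$label))
  sig <- if (comparator == "le") `<=` else `<`
  rows <- list()
  tops <- list()
  for (lab in labels) {
    vox <- intersect(roi_map$voxel_id[roi_map$label == lab], colnames(pvals))
    if (!length(vox)) {
      warning("ROI '", lab, "' has no voxels in the p-value matrix; skipped")
      next
    }
    p <- pvals[snp_id, vox]
    score <- -log10(pmax(p, .Machine$double.xmin))
    ord <- order(-score, vox)
    n_top <- as.integer(ceiling(top_frac * length(vox)))
    keep <- ord[seq_len(n_top)]
    p_top <- p[keep]
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = snp_id, roi = lab, n_voxels = length(vox), n_top = n_top,
      min_p_top = min(p_top), max_p_top = max(p_top),
      activated = all(sig(p_top, alpha))
    )
    tops[[lab]] <- data.frame(voxel_id = vox[keep], p = unname(p_top))
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(snp_id = character(0), roi = character(0),
               n_voxels = integer(0), n_top = integer(0),
               min_p_top = numeric(0), max_p_top = numeric(0),
               activated = logical(0))
  }
  rownames(out) <- NULL
  structure(out, class = c("activation_result", "data.frame"),
            top_voxels = tops, top_frac = top_frac, alpha = alpha)
}
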