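#' Pipeline configuration
#'
#' All thresholds and choices for one end-to-end run, either from a
#' simulation (`sim` is a [sim_config()]) or from files on disk.
#'
#' @param sim Optional [sim_config()]; when given, data are simulated.
#' @param genotypes_path,phenotypes_path,covariates_path TSV paths used when
#'   `sim` is NULL.
#' @param roi_map Data frame (`voxel_id`, `label`) or NULL for a single
#'   whole-brain region labelled "all".
#' @param alpha Voxelwise significance threshold.
#' @param s_grid Support-rate thresholds to mine at.
#' @param algorithm "eclat", "fpgrowth" or "apriori".
#' @param min_confidence Rule flagging threshold.
#' @param roi_labels Labels to analyse (default: all in the map).
#' @param top_frac Activation top fraction.
#' @param hwe_threshold HWE QC cutoff.
#' @param seed Seed echoed into the manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, genotypes_path = NULL,
                            phenotypes_path = NULL, covariates_path = NULL,
                            roi_map = NULL, alpha = 0.05,
                            s_grid = c(0.3, 0.5, 0.7),
                            algorithm = c("eclat", "fpgrowth", "apriori"),
                            min_confidence = 0.8, roi_labels = NULL,
                            top_frac = 0.2, hwe_threshold = 1e-6, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(alpha > 0, alpha < 1, all(s_grid > 0), all(s_grid <= 1),
            min_confidence >= 0, min_confidence <= 1,
            top_frac > 0, top_frac <= 1)
  if (is.null(sim) && (is.null(genotypes_path) || is.null(phenotypes_path))) {
    stop("either a sim_config or genotype/phenotype paths are required")
  }
  structure(
    list(sim = sim, genotypes_path = genotypes_path,
         phenotypes_path = phenotypes_path, covariates_path = covariates_path,
         roi_map = roi_map, alpha = alpha, s_grid = sort(s_grid),
         algorithm = algorithm, min_confidence = min_confidence,
         roi_labels = roi_labels, top_frac = top_frac,
         hwe_threshold = hwe_threshold, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

miner <- function(algorithm) {
  switch(algorithm, eclat = eclat, fpgrowth = fp_growth, apriori = apriori_oracle)
}

#' Run the full pipeline
#'
#' Simulate (or load) genotypes/covariates/phenotypes, HWE-filter the SNPs,
#' run the voxelwise GWAS, build per-ROI transaction databases, mine each at
#' every threshold in `s_grid`, derive association rules at the largest `s`,
#' assess ROI activation for the most frequent SNP, and write every artifact
#' (TSV/basket/JSON) plus a reproducibility manifest under `out_dir`.
#' Deterministic stages are byte-identical across reruns of the same config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return (Invisibly) a list with the in-memory artifacts: `pvals`,
#'   `hwe`, `tds`, `mining` (nested by ROI then s), `rules`, `activation`,
#'   `sweep`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load data"
  res <- tryCatch({
    if (!is.null(config$sim)) {
      study <- simulate_study(config$sim)
      g <- study$genotypes; y <- study$phenotypes; x <- study$covariates
    } else {
      g <- read_matrix_tsv(config$genotypes_path)
      y <- read_matrix_tsv(config$phenotypes_path)
      x <- if (!is.null(config$covariates_path)) {
        read_matrix_tsv(config$covariates_path)
      } else NULL
    }
    if (!is.null(x) && ncol(x) == 0L) x <- NULL

    stage <- "HWE filter"
    hwe <- hwe_filter(g, config$hwe_threshold)
    g <- g[, hwe$kept, drop = FALSE]
    utils::write.table(hwe$results, file.path(out_dir, "hwe_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "voxelwise GWAS"
    pvals <- run_vgwas(g, y, x)
    write_matrix_tsv(pvals, file.path(out_dir, "pvalue_matrix.tsv"))

    roi_map <- config$roi_map %||%
      data.frame(voxel_id = colnames(pvals), label = "all")
    write_roi_map(roi_map, file.path(out_dir, "roi_map.tsv"))
    labels <- config$roi_labels %||% sort(unique(roi_map$label))

    stage <- "transactionalization"
    tds <- list()
    for (lab in labels) {
      sub <- subset_by_roi(pvals, roi_map, lab)
      td <- build_transactions(sub, config$alpha)
      tds[[lab]] <- td
      write_basket(td, file.path(out_dir, paste0("transactions_", lab, ".basket")))
      utils::write.table(support_table(td),
                         file.path(out_dir, paste0("support_", lab, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      message("TD (", lab, "): TD_num = ", td$td_num, ", items = ", length(td$items))
    }

    stage <- "frequent itemset mining"
    mine <- miner(config$algorithm)
    mining <- list()
    for (lab in labels) {
      mining[[lab]] <- list()
      for (s in config$s_grid) {
        r <- mine(tds[[lab]], s)
        mining[[lab]][[as.character(s)]] <- r
        write_mining_result(r, file.path(out_dir, sprintf("fi_%s_s%s.tsv", lab, s)))
        message("mined ", nrow(r), " FIs in ", lab, " at s = ", s)
      }
    }

    stage <- "association rules"
    rules <- list()
    s_rules <- max(config$s_grid)
    for (lab in labels) {
      r <- mining[[lab]][[as.character(s_rules)]]
      rl <- generate_rules(r, tds[[lab]], config$min_confidence)
      rules[[lab]] <- rl
      write_rules_tsv(rl, file.path(out_dir, paste0("rules_", lab, ".tsv")))
    }

    stage <- "ROI activation"
    top_snp <- support_table(build_transactions(pvals, config$alpha))$item[1]
    act <- activated_rois(pvals, roi_map, top_snp, config$top_frac, config$alpha,
                          labels = labels)
    utils::write.table(as.data.frame(act),
                       file.path(out_dir, "activation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "sweep report"
    sweep <- do.call(rbind, lapply(labels, function(lab) {
      cbind(roi = lab, sweep_report(mining[[lab]]))
    }))
    utils::write.table(sweep, file.path(out_dir, "fi_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "manifest"
    manifest <- list(
      package = "snpfim",
      package_version = as.character(utils::packageVersion("snpfim")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      alpha = config$alpha, s_grid = config$s_grid,
      algorithm = config$algorithm, min_confidence = config$min_confidence,
      top_frac = config$top_frac, hwe_threshold = config$hwe_threshold,
      roi_labels = labels,
      simulated = !is.null(config$sim),
      sim = if (!is.null(config$sim)) {
        cfg <- config$sim
        list(n_subjects = cfg$n_subjects, n_snps = cfg$n_snps,
             n_voxels = cfg$n_voxels, noise_sd = cfg$noise_sd,
             n_covariates = cfg$n_covariates, seed = cfg$seed,
             mafs = cfg$mafs,
             blocks = lapply(cfg$blocks, unclass))
      }
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(pvals = pvals, hwe = hwe, tds = tds, mining = mining, rules = rules,
         activation = act, sweep = sweep, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Tidy table of frequent-itemset counts across support thresholds
#'
#' Long-format `(s, k, count)` table over a set of mining results from the
#' same transaction database, with explicit zero rows for sizes absent at a
#' given threshold (so sweep plots show the drop to zero rather than a gap).
#'
#' @param results List of `mining_result` objects sharing one TD.
#' @return Data frame with columns `s`, `k`, `count`.
#' @export
sweep_report <- function(results) {
  stopifnot(length(results) >= 1)
  for (r in results) stopifnot(inherits(r, "mining_result"))
  sums <- vapply(results, function(r) attr(r, "td_checksum"), numeric(1))
  tdn <- vapply(results, function(r) attr(r, "td_num"), numeric(1))
  if (length(unique(sums)) > 1L || length(unique(tdn)) > 1L) {
    stop("mining results come from different transaction databases")
  }
  ks <- sort(unique(c(1L, unlist(lapply(results, function(r) r$k)))))
  rows <- lapply(results, function(r) {
    cb <- count_by_size(r)
    cnt <- stats::setNames(rep(0L, length(ks)), ks)
    if (nrow(cb)) cnt[as.character(cb$k)] <- cb$count
    data.frame(s = attr(r, "s"), k = ks, count = as.integer(cnt))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$s, out$k), ]
  rownames(out) <- NULL
  out
}
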