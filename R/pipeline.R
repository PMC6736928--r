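#' Run the full isochore-stratified analysis on a study bundle
#'
#' End-to-end orchestration: per-window differential test, mDMR/DMR curve and
#' threshold selection (or the conventional p = 0.001 override), DMR calling
#' and merging, isoDMB construction, the four isochore-stratified permutation
#' statistics, DMR-defined gene subsets, and the Monte-Carlo-Wilcoxon GEBI
#' tests for isochore-class and DMR-defined subsets. Every stochastic step
#' derives its seed from the single `seed` argument, so a rerun with the same
#' bundle and seed is identical.
#'
#' @param bundle A study bundle from [simulate_study()], or an equivalently
#'   shaped list built from files read with the `read_*()` family (fields
#'   `layout, isochores, genes, meth_counts, expr_counts, go, snps`; the
#'   `go`/`snps` fields may be `NULL` to skip those statistics).
#' @param p_threshold DMR significance threshold; the default 0.001 is the
#'   conventional choice. Use `p_threshold = NULL` to select it from the
#'   mDMR/DMR curve via [select_p_threshold()].
#' @param thresholds Grid for the mDMR/DMR curve ([default_p_grid()]).
#' @param n_perm Permutations per statistic (default 1000; raise to 10000 for
#'   publication-grade p-values).
#' @param seed Master seed (required).
#' @param min_dmrs,max_gap isoDMB construction parameters ([build_isodmbs()]).
#' @param gebi_statistic `"mean"`, `"cv"` or both.
#' @return List of class `isobias_report`: `window_stats, curve, p_threshold,
#'   dmrs, mdmrs, isodmbs, bias` (one `iso_bias_result` per statistic),
#'   `gene_subsets, gebi` (one `mcw_result` per statistic kind), `manifest`.
#' @export
run_pipeline <- function(bundle, p_threshold = 0.001,
                         thresholds = default_p_grid(), n_perm = 1000,
                         seed = NULL, min_dmrs = 2, max_gap = Inf,
                         gebi_statistic = c("mean", "cv")) {
  if (is.null(seed)) abort("A master `seed` is required.")
  gebi_statistic <- match.arg(gebi_statistic, several.ok = TRUE)
  # distinct, reproducible substreams of the master seed (kept below 2^31)
  sub_seed <- function(k) (seed %% 2097152L) * 1024L + k
  stats <- test_windows(bundle$meth_counts)
  curve <- mdmr_curve(stats, thresholds, layout = bundle$layout)
  if (is.null(p_threshold)) p_threshold <- select_p_threshold(curve)
  dmrs <- call_dmrs(stats, p_threshold)
  mdmrs <- merge_adjacent_dmrs(dmrs)
  blocks <- build_isodmbs(dmrs, min_dmrs = min_dmrs, max_gap = max_gap)

  bias <- list(
    hyper_hypo_ratio = hyper_hypo_ratio(dmrs, bundle$isochores,
                                        n_perm = n_perm, seed = sub_seed(1L)),
    dmr_enrichment = dmr_enrichment(dmrs, bundle$isochores,
                                    n_perm = n_perm, seed = sub_seed(2L))
  )
  if (!is.null(bundle$go) && nrow(bundle$go) > 0) {
    terms <- split(bundle$go$gene_id, bundle$go$term_id)
    bias$go_enrichment <- lapply(seq_along(terms), function(k) {
      go_enrichment(intersect(terms[[k]], bundle$genes$gene_id), bundle$genes,
                    bundle$isochores, n_perm = n_perm,
                    seed = sub_seed(2L + k))
    })
    names(bias$go_enrichment) <- names(terms)
  }
  if (!is.null(bundle$snps) && nrow(bundle$snps) > 0) {
    bias$snp_enrichment <- snp_enrichment(bundle$snps, bundle$isochores,
                                          n_perm = n_perm, seed = sub_seed(512L))
  }

  expressed <- filter_expressed(bundle$expr_counts)
  deltas <- gene_deltas(expressed)
  class_members <- overlap_iso_classes(bundle$genes, bundle$isochores)
  subsets <- lapply(iso_classes(), function(cl) {
    bundle$genes$gene_id[vapply(class_members$iso_classes,
                                function(v) cl %in% v, logical(1))]
  })
  names(subsets) <- iso_classes()
  gs <- dmr_gene_subsets(bundle$genes, dmrs, blocks, layout = bundle$layout)
  for (sub in unique(gs$subset)) {
    for (dir in unique(gs$direction[gs$subset == sub])) {
      subsets[[paste0("subset_", sub, "_", dir)]] <-
        gs$gene_id[gs$subset == sub & gs$direction == dir]
    }
  }
  subsets <- subsets[vapply(subsets, length, integer(1)) > 0]
  gebi <- lapply(setNames(gebi_statistic, gebi_statistic), function(kind) {
    mcw_test(signed_ranks(deltas, kind), subsets,
             n_perm = n_perm, seed = sub_seed(600L))
  })

  structure(
    list(window_stats = stats, curve = curve, p_threshold = p_threshold,
         dmrs = dmrs, mdmrs = mdmrs, isodmbs = blocks, bias = bias,
         gene_subsets = gs, gebi = gebi,
         manifest = list(seed = seed, n_perm = n_perm,
                         p_threshold = p_threshold, min_dmrs = min_dmrs,
                         max_gap = max_gap,
                         package_version = as.character(utils::packageVersion("isobias")),
                         timestamp = format(Sys.time(), tz = "UTC"))),
    class = "isobias_report"
  )
}

#' @export
print.isobias_report <- function(x, ...) {
  cat("Isochore-stratified methylation/expression report\n")
  cat(sprintf("  DMR threshold p <= %g: %d DMRs, %d mDMRs, %d isoDMBs\n",
              x$p_threshold, nrow(x$dmrs), nrow(x$mdmrs), nrow(x$isodmbs)))
  cat(sprintf("  Bias statistics: %s\n", paste(names(x$bias), collapse = ", ")))
  cat(sprintf("  GEBI kinds: %s (%d subsets)\n",
              paste(names(x$gebi), collapse = ", "),
              nrow(x$gebi[[1]])))
  invisible(x)
}
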