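#' Expressed-gene filter
#'
#' Keeps genes deemed expressed in both treatments: read count above 0 in at
#' least `min_replicates` biological replicates of each group.
#'
#' @param counts Expression count tibble: first column `gene_id`, replicate
#'   columns named `replicate:group` with groups `treatment` and `control`.
#' @param min_replicates Minimum positive replicates per group (default 2).
#' @return The filtered count tibble.
#' @export
filter_expressed <- function(counts, min_replicates = 2) {
  design <- count_groups(counts)
  t_cols <- design$column[design$group == "treatment"]
  c_cols <- design$column[design$group == "control"]
  mat <- as.matrix(counts[, -1])
  pos_t <- rowSums(mat[, t_cols, drop = FALSE] > 0)
  pos_c <- rowSums(mat[, c_cols, drop = FALSE] > 0)
  counts[pos_t >= min_replicates & pos_c >= min_replicates, ]
}

#' Per-gene abundance summaries and between-group differences
#'
#' Normalizes counts to counts per million (library size = column sum of the
#' filtered-in matrix), then per gene and group computes the mean CPM (`M`)
#' and the coefficient of variation (`CV`, sample sd over mean), and the
#' differences `delta_m = M_treatment - M_control` and
#' `delta_cv = CV_treatment - CV_control`.
#'
#' @param counts Expression counts, already passed through
#'   [filter_expressed()] (every gene then has a positive mean in each group).
#' @param library_sizes Optional named per-column library sizes; defaults to
#'   the column sums of `counts`.
#' @return Tibble `gene_id, m_treatment, m_control, cv_treatment, cv_control,
#'   delta_m, delta_cv`.
#' @export
gene_deltas <- function(counts, library_sizes = NULL) {
  design <- count_groups(counts)
  t_cols <- design$column[design$group == "treatment"]
  c_cols <- design$column[design$group == "control"]
  if (length(t_cols) < 2 || length(c_cols) < 2) {
    abort("At least 2 replicates per group are required.")
  }
  mat <- as.matrix(counts[, -1])
  if (is.null(library_sizes)) library_sizes <- colSums(mat)
  if (any(library_sizes <= 0)) abort("Library sizes must be > 0.")
  cpm <- sweep(mat, 2, library_sizes[colnames(mat)] / 1e6, "/")
  mt <- rowMeans(cpm[, t_cols, drop = FALSE])
  mc <- rowMeans(cpm[, c_cols, drop = FALSE])
  if (any(mt == 0) || any(mc == 0)) {
    abort("Zero group mean after filtering; apply `filter_expressed()` first.")
  }
  sd_row <- function(cols) apply(cpm[, cols, drop = FALSE], 1, sd)
  cvt <- sd_row(t_cols) / mt
  cvc <- sd_row(c_cols) / mc
  tibble(gene_id = counts[[1]], m_treatment = mt, m_control = mc,
         cv_treatment = cvt, cv_control = cvc,
         delta_m = mt - mc, delta_cv = cvt - cvc)
}

#' Signed ranks of per-gene differences
#'
#' Standard Wilcoxon signed-rank preparation: genes with a zero difference are
#' dropped, the remainder are ranked by absolute difference from lowest to
#' highest (average ranks on ties), and each rank receives the sign of its
#' difference.
#'
#' @param deltas Output of [gene_deltas()].
#' @param statistic `"mean"` to rank `delta_m` (the mGEBI pathway) or `"cv"`
#'   to rank `delta_cv` (cvGEBI); one code path, parameterized.
#' @return Tibble `gene_id, delta, rank, signed_rank` with attribute
#'   `statistic`.
#' @export
signed_ranks <- function(deltas, statistic = c("mean", "cv")) {
  statistic <- match.arg(statistic)
  delta <- if (statistic == "mean") deltas$delta_m else deltas$delta_cv
  keep <- delta != 0
  if (!any(keep)) abort("All differences are zero; nothing to rank.")
  delta <- delta[keep]
  r <- rank(abs(delta), ties.method = "average")
  out <- tibble(gene_id = deltas$gene_id[keep], delta = delta,
                rank = r, signed_rank = sign(delta) * r)
  attr(out, "statistic") <- statistic
  out
}

#' Gene-expression bias index (GEBI) of a gene subset
#'
#' The sum of the subset's signed ranks divided by the largest value that sum
#' could take — the sum of the `k` largest rank magnitudes in the universe,
#' `k` being the subset size — so the index lies in \[-1, 1\] and hits 1
#' (resp. -1) exactly when the subset holds the genes with the largest
#' absolute differences, all positive (resp. all negative).
#'
#' @param ranked Output of [signed_ranks()] (the ranked gene universe).
#' @param subset_ids Character vector of subset gene ids; ids absent from the
#'   ranked universe (e.g. dropped zero-difference genes) are ignored with a
#'   message.
#' @return The index, a single number in \[-1, 1\]; `NA` (with a warning) for
#'   an empty subset.
#' @export
gebi <- function(ranked, subset_ids) {
  idx <- match(unique(subset_ids), ranked$gene_id)
  n_drop <- sum(is.na(idx))
  if (n_drop > 0) {
    inform(sprintf("%d subset gene(s) not in the ranked universe; ignored.", n_drop))
  }
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    warn("Empty subset after matching; GEBI undefined.")
    return(NA_real_)
  }
  denom <- sum(sort(ranked$rank, decreasing = TRUE)[seq_along(idx)])
  sum(ranked$signed_rank[idx]) / denom
}

#' Monte-Carlo-Wilcoxon test of subset expression bias
#'
#' Computes the GEBI of each subset and compares it with GEBIs obtained after
#' randomly rearranging the signed ranks across the gene universe `n_perm`
#' times. One shuffle per draw serves every subset, preserving the
#' cross-subset correlation structure of the null. Empirical p-values follow
#' [empirical_p()] (ties in both tails); percentile bands follow
#' [percentile_band()].
#'
#' @param ranked Output of [signed_ranks()].
#' @param subsets Named list of character vectors of gene ids.
#' @param n_perm Number of signed-rank permutations (default 10000).
#' @param seed Seed for the permutation stream (required).
#' @return Tibble of class `mcw_result`: `subset, n_genes, observed, p_upper,
#'   p_lower, p5, p95, log_obs_p5, log_obs_p95, significant`; attributes
#'   `statistic`, `n_perm`, `seed`. Log-band entries are `NA` for
#'   non-positive observed values (GEBIs may be negative; the band columns
#'   mirror the ratio-statistic report and are mainly useful for plotting).
#' @export
mcw_test <- function(ranked, subsets, n_perm = 10000, seed = NULL) {
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  if (is.null(seed)) abort("A `seed` is required.")
  if (is.null(names(subsets)) || any(names(subsets) == "")) {
    abort("`subsets` must be a named list.")
  }
  s <- ranked$signed_rank
  rk_sorted <- sort(ranked$rank, decreasing = TRUE)
  idx_list <- lapply(subsets, function(ids) {
    i <- match(unique(ids), ranked$gene_id)
    i[!is.na(i)]
  })
  denoms <- vapply(idx_list, function(i) sum(rk_sorted[seq_along(i)]), numeric(1))
  observed <- vapply(seq_along(idx_list), function(k) {
    if (length(idx_list[[k]]) == 0) NA_real_
    else sum(s[idx_list[[k]]]) / denoms[k]
  }, numeric(1))
  null_mat <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sp <- sample(s)
      vapply(seq_along(idx_list), function(k) {
        if (length(idx_list[[k]]) == 0) NA_real_
        else sum(sp[idx_list[[k]]]) / denoms[k]
      }, numeric(1))
    }, numeric(length(idx_list)))
  })
  null_mat <- matrix(null_mat, nrow = length(idx_list))
  rows <- lapply(seq_along(idx_list), function(k) {
    if (is.na(observed[k])) {
      return(tibble(p_upper = NA_real_, p_lower = NA_real_, p5 = NA_real_,
                    p95 = NA_real_, log_obs_p5 = NA_real_,
                    log_obs_p95 = NA_real_, significant = NA))
    }
    ep <- empirical_p(observed[k], null_mat[k, ])
    pb <- percentile_band(observed[k], null_mat[k, ])
    tibble(p_upper = ep$p_upper, p_lower = ep$p_lower, p5 = pb$p5,
           p95 = pb$p95, log_obs_p5 = pb$log_obs_p5,
           log_obs_p95 = pb$log_obs_p95,
           significant = min(ep$p_upper, ep$p_lower) < 0.05)
  })
  out <- cbind(
    tibble(subset = names(subsets),
           n_genes = vapply(idx_list, length, integer(1)),
           observed = observed),
    bind_rows(rows)
  ) %>% as_tibble()
  attr(out, "statistic") <- attr(ranked, "statistic") %||% "mean"
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("mcw_result", class(out))
  out
}

#' DMR-defined gene subsets I, II and III
#'
#' * Subset I: genes with at least one DMR less than `upstream` bp upstream or
#'   less than `downstream` bp downstream of their TSS (strand-aware; see
#'   [tss_windows()]).
#' * Subset II: genes that overlap at least one DMR, plus — for every DMR in
#'   intergenic space — its nearest gene on each side (within `flank_max` bp).
#' * Subset III: genes located within isoDMBs (see [genes_in_isodmbs()]).
#'
#' Each membership carries the direction of the supporting DMR or block, so
#' hyper and hypo subsets can be tested separately.
#'
#' @param genes Gene tibble (`gene_id, chrom, start, end, strand, tss`).
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param blocks isoDMB tibble from [build_isodmbs()]; `NULL` skips subset III.
#' @param upstream,downstream TSS-window extent for subset I (defaults
#'   1500/500 bp).
#' @param flank_max Maximum flanking distance for subset II (default `Inf`).
#' @param layout Optional genome layout for TSS-window clipping.
#' @return Tibble `gene_id, subset (I/II/III), direction (hyper/hypo)`,
#'   distinct rows.
#' @export
dmr_gene_subsets <- function(genes, dmrs, blocks = NULL, upstream = 1500,
                             downstream = 500, flank_max = Inf, layout = NULL) {
  dir_chr <- as.character(dmrs$direction)
  # Subset I: TSS windows overlapping DMRs
  tssw <- tss_windows(genes, upstream, downstream, layout)
  h1 <- overlap_pairs(tssw, dmrs)
  sub1 <- tibble(gene_id = genes$gene_id[h1$query], subset = "I",
                 direction = dir_chr[h1$subject])
  # Subset II: gene-body overlap ...
  h2 <- overlap_pairs(genes, dmrs)
  sub2 <- tibble(gene_id = genes$gene_id[h2$query], subset = "II",
                 direction = dir_chr[h2$subject])
  # ... plus nearest flanking gene on each side of intergenic DMRs
  intergenic <- setdiff(seq_len(nrow(dmrs)), unique(h2$subject))
  flank <- purrr::map_dfr(intergenic, function(j) {
    same <- which(genes$chrom == dmrs$chrom[j])
    if (length(same) == 0) return(NULL)
    d_left <- dmrs$start[j] - genes$end[same]
    d_right <- genes$start[same] - dmrs$end[j]
    out <- NULL
    left_ok <- which(d_left >= 0 & d_left <= flank_max)
    if (length(left_ok) > 0) {
      g <- same[left_ok[which.min(d_left[left_ok])]]
      out <- c(out, genes$gene_id[g])
    }
    right_ok <- which(d_right >= 0 & d_right <= flank_max)
    if (length(right_ok) > 0) {
      g <- same[right_ok[which.min(d_right[right_ok])]]
      out <- c(out, genes$gene_id[g])
    }
    if (is.null(out)) return(NULL)
    tibble(gene_id = out, subset = "II", direction = dir_chr[j])
  })
  out <- bind_rows(sub1, sub2, flank)
  # Subset III: genes within isoDMBs
  if (!is.null(blocks)) {
    s3 <- genes_in_isodmbs(genes, blocks)
    out <- bind_rows(out, tibble(gene_id = s3$gene_id, subset = "III",
                                 direction = as.character(s3$direction)))
  }
  distinct(out)
}
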