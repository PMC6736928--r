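#' Empirical permutation p-values
#'
#' Tail fractions of a permutation null with ties counted in both tails:
#' `p_upper` is the fraction of null values greater than or equal to the
#' observed statistic, `p_lower` the fraction lower than or equal. A result is
#' called significant when either tail is below 0.05, so `p_upper + p_lower`
#' is always at least 1.
#'
#' @param observed Observed statistic (single value).
#' @param null Numeric vector of permuted statistics; `NA` values (undefined
#'   permuted statistics) are dropped.
#' @return Named list `p_upper, p_lower, n_valid`.
#' @export
empirical_p <- function(observed, null) {
  null <- null[!is.na(null)]
  if (length(null) == 0) abort("Empty permutation null.")
  tol <- 1e-12 * max(1, abs(observed))
  list(
    p_upper = mean(null >= observed - tol),
    p_lower = mean(null <= observed + tol),
    n_valid = length(null)
  )
}

#' Log-scale band between the observed statistic and null percentiles
#'
#' The band `(log(observed / p5), log(observed / p95))` drawn in the
#' stacked-panel figures: entirely above zero when the observed statistic
#' exceeds the null's 95th percentile, entirely below zero when it falls
#' under the 5th percentile, and spanning zero otherwise. Percentiles are
#' computed by linear interpolation between order statistics
#' (`quantile(type = 7)`); base-10 logarithms by default.
#'
#' @param observed Observed statistic (> 0; ratio statistics are positive).
#' @param null Numeric null vector (`NA` dropped).
#' @param base Logarithm base (default 10).
#' @return Named list `p5, p95, log_obs_p5, log_obs_p95`; log entries are
#'   `NA` when the observed value or a percentile is not positive.
#' @export
percentile_band <- function(observed, null, base = 10) {
  null <- null[!is.na(null)]
  q <- quantile(null, c(0.05, 0.95), names = FALSE, type = 7)
  lg <- function(x) if (is.na(x) || x <= 0) NA_real_ else log(x, base)
  list(p5 = q[1], p95 = q[2],
       log_obs_p5 = if (is.na(observed) || observed <= 0 || q[1] <= 0)
         NA_real_ else log(observed / q[1], base),
       log_obs_p95 = if (is.na(observed) || observed <= 0 || q[2] <= 0)
         NA_real_ else log(observed / q[2], base))
}

# ---- internal permutation machinery --------------------------------------

# Closure counting, for a label vector, how many items overlap >= 1 isochore
# of each class. `hits` has columns query (item) and subject (isochore row).
# Items overlapping a single isochore take a vectorized path; the few items
# spanning several isochores are de-duplicated per class.
item_class_counter <- function(hits, n_classes = 5L) {
  n_per_item <- table(hits$query)
  multi_items <- as.integer(names(n_per_item)[n_per_item > 1])
  single <- hits$subject[!(hits$query %in% multi_items)]
  multi <- lapply(split(hits$subject, hits$query)[as.character(multi_items)],
                  as.integer)
  function(lab) {
    cnt <- tabulate(lab[single], nbins = n_classes)
    for (idx in multi) {
      cl <- unique(lab[idx])
      cnt[cl] <- cnt[cl] + 1L
    }
    cnt
  }
}

# Shared engine: statistic_fn maps an integer label vector (one label per
# isochore record) to the per-class statistic. Shuffling the labels preserves
# their multiset exactly (a relabeling, not a resampling).
iso_perm_engine <- function(labels_int, statistic_fn, n_perm, seed,
                            extra_cols = NULL) {
  observed <- statistic_fn(labels_int)
  cls <- iso_classes()
  out <- tibble(iso_class = factor(cls, levels = cls), observed = observed)
  if (!is.null(extra_cols)) out <- cbind(extra_cols, out) %>% as_tibble()
  if (n_perm > 0) {
    if (is.null(seed)) abort("A `seed` is required when `n_perm` > 0.")
    if (n_perm < 1) abort("`n_perm` must be >= 1.")
    null_mat <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) statistic_fn(sample(labels_int)),
             numeric(length(cls)))
    })
    per_class <- lapply(seq_along(cls), function(k) {
      nullk <- null_mat[k, ]
      if (is.na(out$observed[k]) || all(is.na(nullk))) {
        return(tibble(p_upper = NA_real_, p_lower = NA_real_, p5 = NA_real_,
                      p95 = NA_real_, log_obs_p5 = NA_real_,
                      log_obs_p95 = NA_real_, significant = NA))
      }
      ep <- empirical_p(out$observed[k], nullk)
      pb <- percentile_band(out$observed[k], nullk)
      tibble(p_upper = ep$p_upper, p_lower = ep$p_lower, p5 = pb$p5,
             p95 = pb$p95, log_obs_p5 = pb$log_obs_p5,
             log_obs_p95 = pb$log_obs_p95,
             significant = min(ep$p_upper, ep$p_lower) < 0.05)
    })
    out <- cbind(out, bind_rows(per_class)) %>% as_tibble()
    attr(out, "n_perm") <- n_perm
    attr(out, "seed") <- seed
  }
  class(out) <- c("iso_bias_result", class(out))
  out
}

iso_labels_int <- function(isochores) {
  lab <- as.integer(factor(as.character(isochores$iso_class),
                           levels = iso_classes()))
  if (anyNA(lab)) abort("Isochore classes must be among L1, L2, H1, H2, H3.")
  lab
}

#' Hyper-/hypomethylated DMR ratio per isochore class
#'
#' For each isochore class the ratio `(u/d) / (U/D)`, where `u` and `d` count
#' hyper- and hypomethylated DMRs overlapping (>= 1 bp) isochores of that
#' class and `U`, `D` count DMRs overlapping any isochore. A DMR spanning two
#' classes counts in both class numerators but once in `U`/`D`. Classes with
#' `d = 0` are undefined (`NA`) and excluded from significance calls.
#'
#' With `n_perm > 0`, significance is assessed against a null obtained by
#' randomly rearranging the isochore class tags (lengths and overlap
#' structure stay with the records) `n_perm` times.
#'
#' @param dmrs DMR tibble (`chrom, start, end, direction`).
#' @param isochores Isochore tibble (`chrom, start, end, iso_class`).
#' @param n_perm Number of tag permutations (0 = observed statistic only).
#' @param seed Seed for the permutation stream (required when `n_perm > 0`).
#' @return An `iso_bias_result` tibble: one row per class with counts,
#'   `observed`, and (when permuted) `p_upper, p_lower, p5, p95,
#'   log_obs_p5, log_obs_p95, significant`.
#' @export
hyper_hypo_ratio <- function(dmrs, isochores, n_perm = 0, seed = NULL) {
  lab <- iso_labels_int(isochores)
  hyper <- dmrs[dmrs$direction == "hyper", ]
  hypo <- dmrs[dmrs$direction == "hypo", ]
  hits_u <- overlap_pairs(hyper, isochores)
  hits_d <- overlap_pairs(hypo, isochores)
  U <- n_distinct(hits_u$query)
  D <- n_distinct(hits_d$query)
  if (U == 0 || D == 0) {
    abort("No hypermethylated or no hypomethylated DMR overlaps any isochore.")
  }
  cnt_u <- item_class_counter(hits_u)
  cnt_d <- item_class_counter(hits_d)
  stat_fn <- function(l) {
    u <- cnt_u(l); d <- cnt_d(l)
    r <- (u / d) / (U / D)
    r[d == 0] <- NA_real_
    r
  }
  extra <- tibble(u = cnt_u(lab), d = cnt_d(lab))
  out <- iso_perm_engine(lab, stat_fn, n_perm, seed, extra_cols = extra)
  attr(out, "statistic") <- "hyper_hypo_ratio"
  out
}

#' DMR enrichment per isochore class
#'
#' For each class the enrichment `(x/X) / (l/L)`: the share of DMRs (hyper and
#' hypo together) overlapping the class relative to the share of cumulative
#' isochore length in the class. Tag permutation reassigns class labels, so
#' both `x` and `l` are recomputed per draw.
#'
#' @inheritParams hyper_hypo_ratio
#' @return An `iso_bias_result` tibble with columns `x`, `class_bp`,
#'   `observed` and permutation columns as in [hyper_hypo_ratio()].
#' @export
dmr_enrichment <- function(dmrs, isochores, n_perm = 0, seed = NULL) {
  lab <- iso_labels_int(isochores)
  len <- isochores$end - isochores$start
  L <- sum(len)
  hits <- overlap_pairs(dmrs, isochores)
  X <- n_distinct(hits$query)
  if (X == 0 || L <= 0) abort("No DMR overlaps any isochore, or zero-length map.")
  cnt_x <- item_class_counter(hits)
  stat_fn <- function(l) {
    x <- cnt_x(l)
    lc <- vapply(1:5, function(k) sum(len[l == k]), numeric(1))
    e <- (x / X) / (lc / L)
    e[lc == 0] <- NA_real_
    e
  }
  extra <- tibble(x = cnt_x(lab),
                  class_bp = vapply(1:5, function(k) sum(len[lab == k]), numeric(1)))
  out <- iso_perm_engine(lab, stat_fn, n_perm, seed, extra_cols = extra)
  attr(out, "statistic") <- "dmr_enrichment"
  out
}

#' GO-term gene enrichment per isochore class
#'
#' For each class the enrichment `(x/n) / (X/N)`: term genes in the class over
#' universe genes in the class, relative to term genes overlapping any
#' isochore over universe genes overlapping any isochore. Gene-class
#' membership is by >= 1 bp overlap.
#'
#' @param term_genes Character vector of gene ids associated with the term
#'   (must be a subset of the universe).
#' @param universe_genes Gene tibble (`gene_id, chrom, start, end`) defining
#'   the universe.
#' @inheritParams hyper_hypo_ratio
#' @return An `iso_bias_result` tibble with columns `x`, `n`, `observed` and
#'   permutation columns as in [hyper_hypo_ratio()].
#' @export
go_enrichment <- function(term_genes, universe_genes, isochores,
                          n_perm = 0, seed = NULL) {
  if (!all(term_genes %in% universe_genes$gene_id)) {
    abort("`term_genes` must be a subset of the universe gene ids.")
  }
  lab <- iso_labels_int(isochores)
  hits_n <- overlap_pairs(universe_genes, isochores)
  term_rows <- which(universe_genes$gene_id %in% term_genes)
  hits_x <- hits_n[hits_n$query %in% term_rows, ]
  N <- n_distinct(hits_n$query)
  X <- n_distinct(hits_x$query)
  if (N == 0 || X == 0) abort("No universe or term gene overlaps any isochore.")
  cnt_n <- item_class_counter(hits_n)
  cnt_x <- item_class_counter(hits_x)
  stat_fn <- function(l) {
    x <- cnt_x(l); nn <- cnt_n(l)
    e <- (x / nn) / (X / N)
    e[nn == 0] <- NA_real_
    e
  }
  extra <- tibble(x = cnt_x(lab), n = cnt_n(lab))
  out <- iso_perm_engine(lab, stat_fn, n_perm, seed, extra_cols = extra)
  attr(out, "statistic") <- "go_enrichment"
  out
}

#' GWAS-SNP enrichment per isochore class
#'
#' For each class the enrichment `(x/X) / (l/L)` where `x` counts SNPs mapping
#' to isochores of the class and `X` counts SNPs mapping to any isochore. A
#' SNP (a point) maps to the single isochore containing its position; SNPs
#' outside every isochore are excluded from `X` (reported via a message).
#'
#' @param snps SNP tibble (`chrom, pos`, 0-based positions).
#' @inheritParams hyper_hypo_ratio
#' @return An `iso_bias_result` tibble with columns `x`, `class_bp`,
#'   `observed` and permutation columns as in [hyper_hypo_ratio()].
#' @export
snp_enrichment <- function(snps, isochores, n_perm = 0, seed = NULL) {
  lab <- iso_labels_int(isochores)
  len <- isochores$end - isochores$start
  L <- sum(len)
  pts <- tibble(chrom = snps$chrom, start = snps$pos, end = snps$pos + 1)
  hits <- overlap_pairs(pts, isochores)
  n_out <- nrow(snps) - n_distinct(hits$query)
  if (n_out > 0) inform(sprintf("%d SNP(s) outside all isochores excluded.", n_out))
  X <- n_distinct(hits$query)
  if (X == 0) abort("No SNP maps to any isochore.")
  snp_iso <- hits$subject  # single isochore per SNP (non-overlapping map)
  stat_fn <- function(l) {
    x <- tabulate(l[snp_iso], nbins = 5)
    lc <- vapply(1:5, function(k) sum(len[l == k]), numeric(1))
    e <- (x / X) / (lc / L)
    e[lc == 0] <- NA_real_
    e
  }
  extra <- tibble(x = tabulate(lab[snp_iso], nbins = 5),
                  class_bp = vapply(1:5, function(k) sum(len[lab == k]), numeric(1)))
  out <- iso_perm_engine(lab, stat_fn, n_perm, seed, extra_cols = extra)
  attr(out, "statistic") <- "snp_enrichment"
  out
}
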