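#' Per-window differential methylation test
#'
#' For each window, pools read counts within each group and applies a
#' two-sided exact binomial test of the treatment share of pooled reads
#' against the treatment share of total library size. The direction of change
#' is the sign of the difference in library-size-normalized group means
#' (counts per million), so a window with equal normalized coverage is tied
#' (direction 0) and can never become a DMR. All-zero windows get p = 1.
#'
#' The per-window engine is deliberately pluggable: every downstream statistic
#' consumes only `(p, direction)` per window.
#'
#' @param counts Window count tibble: columns `chrom, start, end` then one
#'   column per replicate named `replicate:group` with groups `treatment` and
#'   `control`.
#' @param library_sizes Optional named numeric of per-replicate library sizes;
#'   defaults to the column sums of `counts`.
#' @return Tibble `chrom, start, end, p, direction, mean_treatment,
#'   mean_control` with `direction` in {-1, 0, +1} and group means in CPM.
#' @export
test_windows <- function(counts, library_sizes = NULL) {
  design <- count_groups(cbind(counts[, 1], counts[, -(1:3)]))
  if (!setequal(design$group, c("treatment", "control"))) {
    abort("Count columns must carry groups 'treatment' and 'control'.")
  }
  t_cols <- design$column[design$group == "treatment"]
  c_cols <- design$column[design$group == "control"]
  if (length(t_cols) < 2 || length(c_cols) < 2) {
    abort("At least 2 replicates per group are required.")
  }
  mat <- as.matrix(counts[, design$column])
  if (!is.numeric(mat)) abort("Replicate columns must be numeric.")
  if (is.null(library_sizes)) {
    library_sizes <- colSums(mat)
  } else {
    library_sizes <- library_sizes[design$column]
  }
  if (any(library_sizes <= 0)) abort("Library sizes must be > 0.")
  cpm <- sweep(mat, 2, library_sizes / 1e6, "/")
  mean_t <- rowMeans(cpm[, t_cols, drop = FALSE])
  mean_c <- rowMeans(cpm[, c_cols, drop = FALSE])
  direction <- sign(mean_t - mean_c)
  pooled_t <- rowSums(mat[, t_cols, drop = FALSE])
  pooled_c <- rowSums(mat[, c_cols, drop = FALSE])
  p0 <- sum(library_sizes[t_cols]) / sum(library_sizes)
  # windows sharing pooled counts share a p-value: test each distinct pair once
  key <- paste(pooled_t, pooled_c)
  uniq <- !duplicated(key)
  p_for <- vapply(which(uniq), function(i) {
    n <- pooled_t[i] + pooled_c[i]
    if (n == 0) return(1)
    binom.test(pooled_t[i], n, p = p0)$p.value
  }, numeric(1))
  p <- unname(p_for[match(key, key[uniq])])
  p[pooled_t + pooled_c == 0] <- 1
  direction[pooled_t + pooled_c == 0] <- 0
  tibble(chrom = counts$chrom, start = counts$start, end = counts$end,
         p = p, direction = as.integer(direction),
         mean_treatment = mean_t, mean_control = mean_c)
}

#' Call DMRs at a p-value threshold
#'
#' Keeps windows with `p <= p_threshold` and a non-zero direction;
#' hypermethylated means higher normalized coverage in treatment.
#'
#' @param stats Window statistics from [test_windows()].
#' @param p_threshold Significance threshold in (0, 1\]; default 0.001.
#' @return DMR tibble `chrom, start, end, direction, p` with `direction` a
#'   factor (`hyper`, `hypo`) and attribute `p_threshold`.
#' @export
call_dmrs <- function(stats, p_threshold = 0.001) {
  if (p_threshold <= 0 || p_threshold > 1) abort("`p_threshold` must be in (0, 1].")
  keep <- stats$p <= p_threshold & stats$direction != 0
  out <- tibble(
    chrom = stats$chrom[keep], start = stats$start[keep], end = stats$end[keep],
    direction = factor(ifelse(stats$direction[keep] > 0, "hyper", "hypo"),
                       levels = c("hyper", "hypo")),
    p = stats$p[keep]
  )
  out <- arrange(out, .data$chrom, .data$start)
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Merge adjacent same-direction DMRs into mDMRs
#'
#' Maximal runs of DMRs occupying consecutive windows (zero gap) with the same
#' direction of change fuse into one merged record; merging never changes the
#' total number of covered bases.
#'
#' @param dmrs DMR tibble from [call_dmrs()] (distinct windows).
#' @return Tibble `chrom, start, end, direction, n_windows`.
#' @export
merge_adjacent_dmrs <- function(dmrs) {
  if (nrow(dmrs) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  direction = factor(character(), levels = c("hyper", "hypo")),
                  n_windows = integer()))
  }
  d <- arrange(dmrs, .data$chrom, .data$start)
  new_run <- d$chrom != lag(d$chrom, default = "") |
    d$start != lag(d$end, default = -1) |
    as.character(d$direction) != lag(as.character(d$direction), default = "")
  run <- cumsum(new_run)
  d %>%
    group_by(run = run) %>%
    summarise(chrom = first(.data$chrom), start = first(.data$start),
              end = last(.data$end), direction = first(.data$direction),
              n_windows = n(), .groups = "drop") %>%
    select(-"run")
}

#' Default p-value threshold grid
#'
#' 46 log-spaced thresholds between 1e-5 and 1.
#'
#' @param n Number of thresholds.
#' @param from,to Grid range.
#' @return Ascending numeric vector.
#' @export
default_p_grid <- function(n = 46, from = 1e-5, to = 1) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Analytic minimum of the mDMR/DMR ratio
#'
#' If every window of every chromosome were a same-direction DMR, merging
#' would leave one mDMR per chromosome, so the mDMR/DMR ratio attains its
#' floor: number of chromosomes / total number of consecutive,
#' non-overlapping windows. For the GRCm38 set in [grcm38_layout()] and
#' 100-bp windows this is 22 / 27,255,386 = 8.07e-07.
#'
#' @param layout Genome layout tibble.
#' @param window_bp Window size in bp (default 100).
#' @return The floor as a single number.
#' @export
mdmr_floor <- function(layout, window_bp = 100) {
  nrow(layout) / sum(ceiling(layout$length_bp / window_bp))
}

#' mDMR/DMR ratio across a p-value threshold grid
#'
#' For each threshold, calls DMRs, merges adjacent same-direction DMRs and
#' records the ratio of merged to unmerged counts. The ratio approaches 1
#' when newly admitted DMRs are isolated and approaches the analytic floor
#' (see [mdmr_floor()]) when they tile chromosomes.
#'
#' @param stats Window statistics from [test_windows()].
#' @param thresholds Ascending threshold grid; default [default_p_grid()].
#' @param layout Optional genome layout; if given, the floor is attached and
#'   ratios are checked against it.
#' @return Tibble of class `mdmr_curve`: `threshold, n_dmr, n_mdmr, ratio`
#'   (`ratio` is `NA` where no DMR is called), with attribute `floor` when
#'   `layout` is supplied.
#' @export
mdmr_curve <- function(stats, thresholds = default_p_grid(), layout = NULL) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be strictly ascending.")
  }
  s <- arrange(stats, .data$chrom, .data$start)
  rows <- purrr::map_dfr(thresholds, function(thr) {
    keep <- s$p <= thr & s$direction != 0
    n_dmr <- sum(keep)
    if (n_dmr == 0) {
      return(tibble(threshold = thr, n_dmr = 0L, n_mdmr = 0L, ratio = NA_real_))
    }
    # count maximal runs of contiguous same-direction windows (vectorized
    # equivalent of nrow(merge_adjacent_dmrs(call_dmrs(stats, thr))))
    chrom <- s$chrom[keep]; start <- s$start[keep]
    end <- s$end[keep]; dir <- s$direction[keep]
    n <- length(start)
    new_run <- c(TRUE, chrom[-1] != chrom[-n] | start[-1] != end[-n] |
                   dir[-1] != dir[-n])
    n_mdmr <- sum(new_run)
    tibble(threshold = thr, n_dmr = n_dmr, n_mdmr = n_mdmr,
           ratio = n_mdmr / n_dmr)
  })
  if (!is.null(layout)) attr(rows, "floor") <- mdmr_floor(layout)
  class(rows) <- c("mdmr_curve", class(rows))
  rows
}

#' Select the significance threshold from mDMR/DMR curves
#'
#' Returns the smallest grid threshold from which every tissue's mDMR/DMR
#' ratio sequence is non-increasing (allowing increases up to `tolerance`)
#' over all larger thresholds, i.e. the point past which relaxing the
#' threshold only broadens already-identified regions. Undefined ratios
#' (no DMRs called) are skipped when checking monotonicity.
#'
#' @param curves A single `mdmr_curve` or a (named) list of them; all curves
#'   must share the same threshold grid.
#' @param tolerance Maximum tolerated ratio increase (default 0, strict).
#' @return The selected threshold, or `NA` if no grid point qualifies
#'   (cannot occur with the trivial final point, but kept for safety).
#' @export
select_p_threshold <- function(curves, tolerance = 0) {
  if (inherits(curves, "mdmr_curve")) curves <- list(curves)
  grids <- lapply(curves, function(cu) cu$threshold)
  if (length(unique(lapply(grids, function(g) signif(g, 12)))) != 1) {
    abort("All curves must share the same threshold grid.")
  }
  grid <- grids[[1]]
  m <- length(grid)
  ok_from <- function(ratio, j) {
    r <- ratio[j:m]
    r <- r[!is.na(r)]
    if (length(r) < 2) return(TRUE)
    all(diff(r) <= tolerance)
  }
  for (j in seq_len(m)) {
    if (all(vapply(curves, function(cu) ok_from(cu$ratio, j), logical(1)))) {
      return(grid[j])
    }
  }
  NA_real_
}

#' Recurrent-DMR fraction between two tissues
#'
#' Jaccard fraction of DMR windows: the intersection counts windows called in
#' both sets with the same direction of change; the union counts windows
#' called in either set (a shared window with opposite directions contributes
#' to the union only).
#'
#' @param dmrs_a,dmrs_b DMR tibbles from [call_dmrs()] on the same window
#'   grid.
#' @return Fraction in \[0, 1\]; `NA` (with a warning) when both sets are
#'   empty.
#' @export
rdmr_fraction <- function(dmrs_a, dmrs_b) {
  if (nrow(dmrs_a) == 0 && nrow(dmrs_b) == 0) {
    warn("Both DMR sets are empty; recurrent fraction undefined.")
    return(NA_real_)
  }
  key_a <- paste(dmrs_a$chrom, dmrs_a$start)
  key_b <- paste(dmrs_b$chrom, dmrs_b$start)
  dir_a <- as.character(dmrs_a$direction)
  dir_b <- as.character(dmrs_b$direction)
  shared <- intersect(key_a, key_b)
  same_dir <- sum(dir_a[match(shared, key_a)] == dir_b[match(shared, key_b)])
  same_dir / length(union(key_a, key_b))
}
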