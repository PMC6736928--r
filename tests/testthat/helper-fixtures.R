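# Shared fixture builders and independent oracles.

# A 5-class isochore map tiling one chromosome in 1-kb blocks.
tiny_isochores <- function(chrom = "chr1") {
  tibble::tibble(
    chrom = chrom,
    start = seq(0, 4000, by = 1000),
    end = seq(1000, 5000, by = 1000),
    iso_class = factor(c("L1", "L2", "H1", "H2", "H3"),
                       levels = c("L1", "L2", "H1", "H2", "H3")),
    gc = c(0.33, 0.39, 0.43, 0.49, 0.56),
    length_bp = 1000
  )
}

# n_hyper/n_hypo DMR windows placed inside the given isochore classes.
dmrs_in_classes <- function(hyper_classes, hypo_classes, iso = tiny_isochores()) {
  place <- function(classes, dir) {
    if (length(classes) == 0) return(NULL)
    rows <- match(classes, as.character(iso$iso_class))
    # spread multiple DMRs within one isochore at 100-bp offsets
    off <- stats::ave(seq_along(rows), rows, FUN = seq_along) - 1
    tibble::tibble(
      chrom = iso$chrom[rows],
      start = iso$start[rows] + off * 100,
      end = iso$start[rows] + off * 100 + 100,
      direction = factor(dir, levels = c("hyper", "hypo")),
      p = 1e-4
    )
  }
  dplyr::bind_rows(place(hyper_classes, "hyper"), place(hypo_classes, "hypo"))
}

# Window count table with explicit per-replicate counts.
# t_counts/c_counts: matrices (windows x replicates).
window_counts <- function(t_counts, c_counts, chrom = "chr1") {
  t_counts <- rbind(t_counts); c_counts <- rbind(c_counts)
  n <- nrow(t_counts)
  out <- tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * 100,
                        end = seq_len(n) * 100)
  for (j in seq_len(ncol(t_counts))) out[[sprintf("t%d:treatment", j)]] <- t_counts[, j]
  for (j in seq_len(ncol(c_counts))) out[[sprintf("c%d:control", j)]] <- c_counts[, j]
  out
}

# All permutations of a vector (exhaustive-enumeration oracle; n <= 7).
perm_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(perm_all(v[-i]), function(p) c(v[i], p))
  }))
}

# Brute-force per-base overlap oracle: classes of isochores sharing >= 1 base
# with the query (for instances of a few kb only).
overlap_classes_bruteforce <- function(query, isochores) {
  pos <- seq(query$start, query$end - 1)
  hit <- vapply(seq_len(nrow(isochores)), function(i) {
    isochores$chrom[i] == query$chrom &&
      any(pos >= isochores$start[i] & pos < isochores$end[i])
  }, logical(1))
  sort(unique(as.character(isochores$iso_class[hit])))
}

# Exact two-sided binomial p-value by tail enumeration (minimum-likelihood
# rule), independent of stats::binom.test.
binom_two_sided_exact <- function(x, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}
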