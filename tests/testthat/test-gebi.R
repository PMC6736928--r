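expr_counts <- function(t_counts, c_counts, ids = NULL) {
  t_counts <- rbind(t_counts); c_counts <- rbind(c_counts)
  out <- tibble::tibble(gene_id = ids %||% paste0("g", seq_len(nrow(t_counts))))
  for (j in seq_len(ncol(t_counts))) out[[sprintf("t%d:treatment", j)]] <- t_counts[, j]
  for (j in seq_len(ncol(c_counts))) out[[sprintf("c%d:control", j)]] <- c_counts[, j]
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("expressed filter requires positive counts in two replicates per group", {
  cnt <- expr_counts(
    rbind(c(0, 0, 1, 2), c(5, 5, 5, 5), c(0, 0, 0, 0)),
    rbind(c(3, 0, 0, 1), c(9, 0, 0, 0), c(0, 0, 0, 0)),
    ids = c("kept", "dropped_control", "all_zero"))
  expect_equal(filter_expressed(cnt)$gene_id, "kept")
})

test_that("per-gene summaries use CPM means and coefficients of variation", {
  libs <- setNames(rep(1e6, 4),
                   c("t1:treatment", "t2:treatment", "c1:control", "c2:control"))
  cnt <- expr_counts(c(10, 30), c(15, 25))
  d <- gene_deltas(cnt, library_sizes = libs)
  expect_equal(d$m_treatment, 20)
  expect_equal(d$cv_treatment, sd(c(10, 30)) / 20)  # ~0.7071
  expect_equal(d$delta_m, 0)
  # identical groups -> zero differences
  cnt2 <- expr_counts(c(10, 30), c(10, 30))
  d2 <- gene_deltas(cnt2, library_sizes = libs)
  expect_equal(c(d2$delta_m, d2$delta_cv), c(0, 0))
  # doubling one library halves that replicate's CPM contribution
  libs2 <- libs; libs2["t1:treatment"] <- 2e6
  d3 <- gene_deltas(cnt, library_sizes = libs2)
  expect_equal(d3$m_treatment, mean(c(10 / 2, 30)))
})

test_that("CPM normalization agrees with edgeR", {
  skip_if_not_installed("edgeR")
  withr::with_seed(2, {
    mat <- matrix(rpois(40, 50), nrow = 10)
    colnames(mat) <- c("t1:treatment", "t2:treatment", "c1:control", "c2:control")
    cnt <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:10)),
                            tibble::as_tibble(mat))
    d <- gene_deltas(cnt)
    ref <- edgeR::cpm(mat, lib.size = colSums(mat))
    expect_equal(d$m_treatment, unname(rowMeans(ref[, 1:2])))
    expect_equal(d$m_control, unname(rowMeans(ref[, 3:4])))
  })
})

test_that("signed ranks drop zeros, average ties, and carry signs", {
  mk <- function(dm) tibble::tibble(gene_id = paste0("g", seq_along(dm)),
                                    m_treatment = 1, m_control = 1,
                                    cv_treatment = 1, cv_control = 1,
                                    delta_m = dm, delta_cv = dm)
  r1 <- signed_ranks(mk(c(0.1, -0.3, 0.2)))
  expect_equal(r1$signed_rank, c(1, -3, 2))
  r2 <- signed_ranks(mk(c(0.2, -0.2, 0.5)))
  expect_equal(r2$signed_rank, c(1.5, -1.5, 3))
  r3 <- signed_ranks(mk(c(0, 0.4)))
  expect_equal(r3$gene_id, "g2")
  expect_equal(r3$signed_rank, 1)
  expect_error(signed_ranks(mk(c(0, 0))), "zero")
})

test_that("GEBI normalizes subset rank sums to [-1, 1]", {
  ranked <- tibble::tibble(gene_id = c("a", "b", "c"),
                           delta = c(0.1, -0.3, 0.2),
                           rank = c(1, 3, 2), signed_rank = c(1, -3, 2))
  expect_equal(gebi(ranked, c("a", "c")), 3 / 5)
  # top-k |delta| genes, all positive -> exactly 1; all negative -> -1
  ranked2 <- ranked; ranked2$signed_rank <- c(1, 3, 2)
  expect_equal(gebi(ranked2, c("b", "c")), 1)
  ranked3 <- ranked; ranked3$signed_rank <- c(-1, -3, -2)
  expect_equal(gebi(ranked3, c("b", "c")), -1)
  expect_warning(na <- gebi(ranked, character(0)), "Empty")
  expect_true(is.na(na))
})

test_that("GEBI magnitude never exceeds 1 and complements sum to the total", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      deltas <- tibble::tibble(
        gene_id = paste0("g", 1:n), m_treatment = 1, m_control = 1,
        cv_treatment = 1, cv_control = 1,
        delta_m = rnorm(n), delta_cv = rnorm(n))
      ranked <- signed_ranks(deltas)
      k <- sample(seq_len(n - 1), 1)
      sub <- sample(ranked$gene_id, k)
      comp <- setdiff(ranked$gene_id, sub)
      expect_lte(abs(gebi(ranked, sub)), 1)
      s_sub <- sum(ranked$signed_rank[match(sub, ranked$gene_id)])
      s_comp <- sum(ranked$signed_rank[match(comp, ranked$gene_id)])
      expect_equal(s_sub + s_comp, sum(ranked$signed_rank))
    }
  })
})

test_that("MCW permutation test is seeded, order-invariant, and tie-correct", {
  withr::with_seed(23, {
    deltas <- tibble::tibble(
      gene_id = paste0("g", 1:30), m_treatment = 1, m_control = 1,
      cv_treatment = 1, cv_control = 1,
      delta_m = rnorm(30), delta_cv = rnorm(30))
  })
  ranked <- signed_ranks(deltas)
  subs <- list(s1 = paste0("g", 1:10), all = paste0("g", 1:30))
  m1 <- mcw_test(ranked, subs, n_perm = 200, seed = 5)
  m2 <- mcw_test(ranked, subs, n_perm = 200, seed = 5)
  expect_equal(m1, m2)
  # subset = universe: permutation-invariant -> both tails 1
  expect_equal(c(m1$p_upper[2], m1$p_lower[2]), c(1, 1))
  # gene input order does not change the indices
  shuffled <- signed_ranks(deltas[sample(30), ])
  m3 <- mcw_test(shuffled, subs, n_perm = 200, seed = 5)
  expect_equal(m3$observed, m1$observed)
  expect_error(mcw_test(ranked, subs, n_perm = 0, seed = 1), ">= 1")
  expect_error(mcw_test(ranked, subs, n_perm = 10), "seed")
})

test_that("Monte-Carlo GEBI p-values converge to exhaustive enumeration", {
  deltas <- tibble::tibble(
    gene_id = paste0("g", 1:6), m_treatment = 1, m_control = 1,
    cv_treatment = 1, cv_control = 1,
    delta_m = c(0.5, -0.2, 0.9, -1.4, 0.3, 0.1), delta_cv = 0.1)
  ranked <- signed_ranks(deltas)
  sub <- c("g1", "g3")
  n_perm <- 4000
  m <- mcw_test(ranked, list(s = sub), n_perm = n_perm, seed = 31)
  idx <- match(sub, ranked$gene_id)
  denom <- sum(sort(ranked$rank, decreasing = TRUE)[1:2])
  null_exact <- vapply(perm_all(ranked$signed_rank), function(s) {
    sum(s[idx]) / denom
  }, numeric(1))
  p_exact <- mean(null_exact >= m$observed - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(m$p_upper - p_exact), 3 * se + 1e-9)
})

test_that("DMR-defined gene subsets follow the I/II/III rules", {
  genes <- tibble::tibble(
    gene_id = c("promo", "far", "host", "left", "right"),
    chrom = "chr1",
    start = c(10000, 40000, 60000, 80000, 95000),
    end = c(12000, 42000, 65000, 82000, 97000),
    strand = c("+", "+", "+", "+", "+"))
  genes$tss <- genes$start
  mk <- function(starts, dirs) tibble::tibble(
    chrom = "chr1", start = starts, end = starts + 100,
    direction = factor(dirs, levels = c("hyper", "hypo")), p = 1e-4)
  dmrs <- mk(c(9000, 37000, 61000, 90000), # 1 kb upstream of promo TSS;
             c("hyper", "hyper", "hypo", "hyper")) # 3 kb upstream of far;
  # inside host; intergenic between left and right
  subs <- dmr_gene_subsets(genes, dmrs, blocks = NULL)
  s1 <- subs$gene_id[subs$subset == "I"]
  expect_setequal(s1, "promo")                      # within 1500 bp upstream
  s2 <- subs$gene_id[subs$subset == "II"]
  # host overlaps; every intergenic DMR recruits its nearest gene per side
  expect_setequal(s2, c("promo", "far", "host", "left", "right"))
  # flank distance cap removes remote neighbours
  subs2 <- dmr_gene_subsets(genes, dmrs, blocks = NULL, flank_max = 3000)
  expect_setequal(subs2$gene_id[subs2$subset == "II"],
                  c("promo", "far", "host"))
  # subset III carries block directions
  blocks <- tibble::tibble(chrom = "chr1", start = 59000, end = 66000,
                           direction = factor("hypo",
                                              levels = c("hyper", "hypo")),
                           n_dmrs = 2L)
  subs3 <- dmr_gene_subsets(genes, dmrs, blocks = blocks)
  s3 <- subs3[subs3$subset == "III", ]
  expect_equal(s3$gene_id, "host")
  expect_equal(s3$direction, "hypo")
})
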