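test_that("hyper/hypo ratio arithmetic matches hand counts", {
  iso <- tiny_isochores()
  # H3: u = 3, d = 1; genome-wide U = 6, D = 6 -> ratio 3
  dmrs <- dmrs_in_classes(hyper_classes = c("H3", "H3", "H3", "L1", "L1", "L2"),
                          hypo_classes = c("H3", "L2", "L2", "H1", "H1", "H2"))
  r <- hyper_hypo_ratio(dmrs, iso)
  expect_equal(r$observed[r$iso_class == "H3"], 3)
  expect_equal(r$u[r$iso_class == "H3"], 3)
  expect_equal(r$d[r$iso_class == "H3"], 1)
  # balanced directions everywhere -> all ratios 1
  bal <- dmrs_in_classes(iso_classes(), iso_classes())
  expect_equal(hyper_hypo_ratio(bal, iso)$observed, rep(1, 5))
  # d = 0 in a class -> undefined, not an error
  r2 <- hyper_hypo_ratio(dmrs_in_classes(c("H3", "L1"), c("L1", "L1")), iso)
  expect_true(is.na(r2$observed[r2$iso_class == "H3"]))
  # no hypo DMRs at all -> analysis-level error
  expect_error(hyper_hypo_ratio(dmrs_in_classes(c("H3", "L1"), character(0)),
                                iso), "hypomethylated")
})

test_that("DMR enrichment matches the length-share formula", {
  # H3 holds 30% of the length; 6 of 10 DMRs in H3 -> enrichment 2
  iso <- tibble::tibble(
    chrom = "chr1", start = c(0, 7000), end = c(7000, 10000),
    iso_class = factor(c("L1", "H3"), levels = iso_classes()),
    gc = c(0.3, 0.6))
  starts <- c(seq(0, 300, by = 100), seq(7000, 7500, by = 100))
  dmrs <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 100,
                         direction = factor(rep(c("hyper", "hypo"), 5),
                                            levels = c("hyper", "hypo")),
                         p = 1e-4)
  e <- dmr_enrichment(dmrs, iso)
  expect_equal(e$observed[e$iso_class == "H3"], (6 / 10) / 0.3)
  expect_equal(e$observed[e$iso_class == "L1"], (4 / 10) / 0.7)
  expect_true(all(is.na(e$observed[!e$iso_class %in% c("L1", "H3")])))
})

test_that("single-class-overlap enrichments satisfy the conservation identity", {
  withr::with_seed(21, {
    iso <- tiny_isochores()
    starts <- sample(seq(0, 4900, by = 100), 30)
    dmrs <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 100,
                           direction = factor(sample(c("hyper", "hypo"), 30,
                                                     replace = TRUE),
                                              levels = c("hyper", "hypo")),
                           p = 1e-4)
    e <- dmr_enrichment(dmrs, iso)
    lL <- e$class_bp / sum(e$class_bp)
    expect_equal(sum(e$observed * lL), 1)
  })
})

test_that("GO enrichment matches the two-ratio formula", {
  iso <- tiny_isochores()
  # universe: 10 genes, 4 in H3; term: 5 genes, 3 in H3 -> (3/4)/(5/10) = 1.5
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:10), chrom = "chr1",
    start = c(4000, 4100, 4200, 4300, 0, 200, 1000, 2000, 3000, 3200),
    end = c(4050, 4150, 4250, 4350, 100, 300, 1100, 2100, 3100, 3300))
  term <- c("g1", "g2", "g3", "g5", "g7")
  e <- go_enrichment(term, genes, iso)
  expect_equal(e$observed[e$iso_class == "H3"], 1.5)
  # term = universe -> enrichment 1 wherever defined
  e2 <- go_enrichment(genes$gene_id, genes, iso)
  expect_true(all(e2$observed[!is.na(e2$observed)] == 1))
  expect_error(go_enrichment("nope", genes, iso), "subset")
})

test_that("SNP enrichment maps points to single isochores", {
  iso <- tibble::tibble(
    chrom = "chr1", start = c(0, 7000), end = c(7000, 10000),
    iso_class = factor(c("L1", "H3"), levels = iso_classes()),
    gc = c(0.3, 0.6))
  snps <- tibble::tibble(chrom = "chr1",
                         pos = c(seq(10, 50, by = 10), seq(7010, 7060, by = 10)),
                         trait = "t")
  e <- snp_enrichment(snps, iso)
  expect_equal(e$observed[e$iso_class == "H3"], (6 / 11) / 0.3)
  # SNPs outside all isochores are excluded from X
  snps2 <- dplyr::bind_rows(snps, tibble::tibble(chrom = "chr2", pos = 5,
                                                 trait = "t"))
  expect_message(e2 <- snp_enrichment(snps2, iso), "excluded")
  expect_equal(e2$observed, e$observed)
})

test_that("empirical p-values count ties in both tails", {
  ep <- empirical_p(5, 1:10)
  expect_equal(ep$p_upper, 0.6)
  expect_equal(ep$p_lower, 0.5)
  ep2 <- empirical_p(11, 1:10)
  expect_equal(c(ep2$p_upper, ep2$p_lower), c(0, 1))
  ep3 <- empirical_p(3, rep(3, 10))
  expect_equal(c(ep3$p_upper, ep3$p_lower), c(1, 1))
  expect_gte(ep$p_upper + ep$p_lower, 1)
})

test_that("percentile bands sit relative to zero as significance dictates", {
  null <- rep(c(1, 4), each = 50)  # p5 = 1, p95 = 4 under type-7 quantiles
  b1 <- percentile_band(2, null)
  expect_equal(b1$log_obs_p5, log10(2))
  expect_equal(b1$log_obs_p95, log10(0.5))
  expect_true(b1$log_obs_p5 > 0 && b1$log_obs_p95 < 0)  # spans zero
  b2 <- percentile_band(5, null)
  expect_true(b2$log_obs_p5 > 0 && b2$log_obs_p95 > 0)  # significant high
  b3 <- percentile_band(0.5, null)
  expect_true(b3$log_obs_p5 < 0 && b3$log_obs_p95 < 0)  # significant low
  expect_true(is.na(percentile_band(-1, null)$log_obs_p5))
})

test_that("tag permutation is a seeded relabeling with sane degenerate limits", {
  iso <- tiny_isochores()
  dmrs <- dmrs_in_classes(c("H3", "H3", "L1"), c("L1", "L2", "H3"))
  r1 <- hyper_hypo_ratio(dmrs, iso, n_perm = 50, seed = 7)
  r2 <- hyper_hypo_ratio(dmrs, iso, n_perm = 50, seed = 7)
  expect_equal(r1, r2)  # deterministic per seed
  expect_error(hyper_hypo_ratio(dmrs, iso, n_perm = 50), "seed")
  # single-class map: statistic invariant under relabeling -> p = 1 both tails
  iso1 <- iso; iso1$iso_class <- factor("H3", levels = iso_classes())
  e <- dmr_enrichment(dmrs, iso1, n_perm = 20, seed = 1)
  h3 <- e[e$iso_class == "H3", ]
  expect_equal(c(h3$p_upper, h3$p_lower), c(1, 1))
  # statistics invariant to record order of inputs
  r3 <- hyper_hypo_ratio(dmrs[sample(nrow(dmrs)), ],
                         iso[sample(nrow(iso)), ], n_perm = 0)
  expect_equal(r3$observed, hyper_hypo_ratio(dmrs, iso)$observed)
})

test_that("Monte-Carlo tag p-values converge to exhaustive enumeration", {
  iso <- tibble::tibble(
    chrom = "chr1", start = seq(0, 5000, by = 1000),
    end = seq(1000, 6000, by = 1000),
    iso_class = factor(c("L1", "L1", "H3", "H3", "H3", "L2"),
                       levels = iso_classes()),
    gc = c(0.3, 0.31, 0.6, 0.61, 0.62, 0.39))
  starts <- c(0, 100, 2000, 3000, 4000, 4100, 5000)
  dmrs <- tibble::tibble(
    chrom = "chr1", start = starts, end = starts + 100,
    direction = factor(c("hyper", "hypo", "hyper", "hyper", "hypo", "hyper",
                         "hypo"), levels = c("hyper", "hypo")),
    p = 1e-4)
  n_perm <- 4000
  mc <- dmr_enrichment(dmrs, iso, n_perm = n_perm, seed = 13)
  # exhaustive null over all 6! label orderings, via an independent
  # per-class recomputation of (x/X)/(l/L)
  labs <- as.character(iso$iso_class)
  len <- iso$end - iso$start
  enrich_for <- function(lab, cls) {
    iso2 <- iso; iso2$iso_class <- factor(lab, levels = iso_classes())
    hit <- vapply(seq_len(nrow(dmrs)), function(i) {
      any(lab == cls & iso2$chrom == dmrs$chrom[i] &
            pmax(iso2$start, dmrs$start[i]) < pmin(iso2$end, dmrs$end[i]))
    }, logical(1))
    x <- sum(hit); X <- nrow(dmrs)
    lc <- sum(len[lab == cls])
    if (lc == 0) return(NA_real_)
    (x / X) / (lc / sum(len))
  }
  for (cls in c("L1", "H3")) {
    obs <- mc$observed[mc$iso_class == cls]
    null_exact <- vapply(perm_all(labs), enrich_for, numeric(1), cls = cls)
    null_exact <- null_exact[!is.na(null_exact)]
    p_exact <- mean(null_exact >= obs - 1e-12)
    se <- sqrt(p_exact * (1 - p_exact) / n_perm)
    expect_lt(abs(mc$p_upper[mc$iso_class == cls] - p_exact), 3 * se + 1e-9)
  }
})
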