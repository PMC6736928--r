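#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the simulator: genome geometry, isochore mosaic,
#' gene placement, negative-binomial count noise, and the planted
#' class-specific methylation-direction and expression effects that give
#' downstream stages a known ground truth. Defaults emulate the study design
#' the pipeline targets: consecutive non-overlapping 100-bp methylation
#' windows, 5 biological replicates per group, overdispersed counts, a
#' five-class isochore mosaic, a hypermethylation bias planted in H3 and a
#' hypomethylation bias in L1, and expression shifts of +0.5 (H3) and -0.5
#' (L1) on the natural-log scale.
#'
#' @param seed Master seed; each generator stage derives its own fixed
#'   substream from it, so regenerating one table never perturbs another.
#' @param n_chroms,chrom_length Number of chromosomes and length of each (bp).
#' @param isochore_length_mean,isochore_length_sd,isochore_length_min
#'   Normal (truncated at the minimum) isochore length distribution, bp.
#' @param class_proportions Named numeric (L1..H3), expected genome fraction
#'   per class; must sum to 1.
#' @param genes_per_mb Mean gene density, genes per Mb.
#' @param gene_class_weights Named relative gene-density weights per class.
#' @param gene_length_mean,gene_length_min Gene length distribution, bp.
#' @param replicates_per_group Biological replicates per group (>= 2).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param window_bp Methylation window size, bp.
#' @param window_mu_meanlog,window_mu_sdlog Log-normal per-window baseline
#'   mean coverage (coverage heterogeneity).
#' @param meth_diff_fraction Named per-class fraction of windows that are
#'   truly differential.
#' @param meth_hyper_prob Named per-class probability that a differential
#'   window is hypermethylated (vs hypomethylated).
#' @param meth_effect_fold Fold-change applied to the treatment mean of a
#'   differential window (multiplied if hyper, divided if hypo).
#' @param expr_mu_meanlog,expr_mu_sdlog Log-normal per-gene baseline mean.
#' @param expr_lfc_mean,expr_lfc_sd Named per-class mean and common sd of the
#'   planted natural-log fold change applied to treatment expression.
#' @param library_size_cv Coefficient of variation of per-replicate library
#'   scale factors.
#' @param go_terms Named list: term id -> named per-class sampling weights
#'   used to draw class-biased gene sets.
#' @param go_term_size Genes per GO term.
#' @param snp_density_per_mb Named per-class SNP density (SNPs per Mb).
#' @param gc_boundaries GC boundaries used to assign class-consistent GC
#'   values; see [default_gc_boundaries()].
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(
    seed = 1L,
    n_chroms = 2L,
    chrom_length = 1e6,
    isochore_length_mean = 5e4,
    isochore_length_sd = 2e4,
    isochore_length_min = 1e4,
    class_proportions = c(L1 = 0.2, L2 = 0.2, H1 = 0.2, H2 = 0.2, H3 = 0.2),
    genes_per_mb = 100,
    gene_class_weights = c(L1 = 1, L2 = 1, H1 = 1, H2 = 1, H3 = 1),
    gene_length_mean = 5e3,
    gene_length_min = 500,
    replicates_per_group = 5L,
    nb_dispersion = 0.05,
    window_bp = 100L,
    window_mu_meanlog = log(50),
    window_mu_sdlog = 0.5,
    meth_diff_fraction = c(L1 = 0.2, L2 = 0.2, H1 = 0.2, H2 = 0.2, H3 = 0.2),
    meth_hyper_prob = c(L1 = 0.1, L2 = 0.5, H1 = 0.5, H2 = 0.5, H3 = 0.9),
    meth_effect_fold = 4,
    expr_mu_meanlog = log(200),
    expr_mu_sdlog = 1,
    expr_lfc_mean = c(L1 = -0.5, L2 = 0, H1 = 0, H2 = 0, H3 = 0.5),
    expr_lfc_sd = 0.2,
    library_size_cv = 0.1,
    go_terms = list(
      uniform_term = c(L1 = 1, L2 = 1, H1 = 1, H2 = 1, H3 = 1),
      gc_biased_term = c(L1 = 0, L2 = 0, H1 = 0.2, H2 = 0.8, H3 = 1)
    ),
    go_term_size = 50L,
    snp_density_per_mb = c(L1 = 50, L2 = 50, H1 = 50, H2 = 50, H3 = 50),
    gc_boundaries = default_gc_boundaries()) {
  cls <- iso_classes()
  expand_by_class <- function(x, nm) {
    if (length(x) == 1) x <- setNames(rep(x, 5), cls)
    if (is.null(names(x)) && length(x) == 5) names(x) <- cls
    if (!setequal(names(x), cls)) abort(sprintf("`%s` must be named by the 5 classes.", nm))
    x[cls]
  }
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = chrom_length,
    isochore_length_mean = isochore_length_mean,
    isochore_length_sd = isochore_length_sd,
    isochore_length_min = isochore_length_min,
    class_proportions = expand_by_class(class_proportions, "class_proportions"),
    genes_per_mb = genes_per_mb,
    gene_class_weights = expand_by_class(gene_class_weights, "gene_class_weights"),
    gene_length_mean = gene_length_mean, gene_length_min = gene_length_min,
    replicates_per_group = as.integer(replicates_per_group),
    nb_dispersion = nb_dispersion, window_bp = as.integer(window_bp),
    window_mu_meanlog = window_mu_meanlog, window_mu_sdlog = window_mu_sdlog,
    meth_diff_fraction = expand_by_class(meth_diff_fraction, "meth_diff_fraction"),
    meth_hyper_prob = expand_by_class(meth_hyper_prob, "meth_hyper_prob"),
    meth_effect_fold = meth_effect_fold,
    expr_mu_meanlog = expr_mu_meanlog, expr_mu_sdlog = expr_mu_sdlog,
    expr_lfc_mean = expand_by_class(expr_lfc_mean, "expr_lfc_mean"),
    expr_lfc_sd = expr_lfc_sd, library_size_cv = library_size_cv,
    go_terms = go_terms, go_term_size = as.integer(go_term_size),
    snp_density_per_mb = expand_by_class(snp_density_per_mb, "snp_density_per_mb"),
    gc_boundaries = gc_boundaries
  )
  probs <- c(cfg$class_proportions, cfg$meth_diff_fraction, cfg$meth_hyper_prob)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9) {
    abort("`class_proportions` must sum to 1.")
  }
  if (cfg$replicates_per_group < 2) {
    abort("`replicates_per_group` must be >= 2 (required by the expressed-gene filter).")
  }
  if (cfg$gene_length_mean >= cfg$isochore_length_mean) {
    abort("Infeasible config: mean gene length must be below mean isochore length.")
  }
  structure(cfg, class = "simulation_config")
}

# Fixed per-stage substreams of the master seed (kept below 2^31).
stage_seed <- function(config, stage) {
  offset <- c(genome = 1L, methylation = 2L, expression = 3L, annotation = 4L)[[stage]]
  (config$seed %% 536870912L) * 4L + offset
}

# Class-consistent GC value: uniform inside the class's GC bin.
draw_gc <- function(iso_class, boundaries) {
  lo <- c(max(boundaries[1] - 0.07, 0), boundaries)[as.integer(iso_class)]
  hi <- c(boundaries, min(boundaries[4] + 0.07, 1))[as.integer(iso_class)]
  runif(length(iso_class), lo, hi)
}

#' Simulate a genome: layout, isochore mosaic and gene annotation
#'
#' Isochores tile each chromosome without gaps or overlaps; lengths are drawn
#' from a truncated normal and the last isochore is clipped to the chromosome
#' end. Classes are drawn independently with the configured proportions, so
#' realized length proportions converge to `class_proportions` for large
#' genomes. Genes are placed wholly inside isochores (Poisson counts with
#' class-weighted density), giving each gene an unambiguous true class.
#'
#' @param config A [simulation_config()].
#' @return List with `layout`, `isochores` (with `gc`, `iso_class`,
#'   `length_bp`) and `genes` (with `strand`, `tss` and true `iso_class`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(stage_seed(config, "genome"), {
    layout <- genome_layout(paste0("chr", seq_len(config$n_chroms)),
                            rep(config$chrom_length, config$n_chroms))
    isochores <- purrr::map_dfr(seq_len(nrow(layout)), function(i) {
      chrom <- layout$chrom[i]; L <- layout$length_bp[i]
      n_guess <- ceiling(L / config$isochore_length_min) + 1
      lens <- pmax(round(rnorm(n_guess, config$isochore_length_mean,
                               config$isochore_length_sd)),
                   config$isochore_length_min)
      ends <- pmin(cumsum(lens), L)
      keep <- c(TRUE, ends[-length(ends)] < L)
      ends <- ends[keep]
      ends <- ends[!duplicated(ends)]
      starts <- c(0, ends[-length(ends)])
      cls <- factor(
        sample(iso_classes(), length(ends), replace = TRUE,
               prob = config$class_proportions),
        levels = iso_classes()
      )
      tibble(chrom = chrom, start = starts, end = ends, iso_class = cls)
    })
    isochores$gc <- draw_gc(isochores$iso_class, config$gc_boundaries)
    isochores$length_bp <- isochores$end - isochores$start
    # genes wholly inside isochores, density proportional to class weight
    w <- config$gene_class_weights / mean(config$gene_class_weights)
    lambda <- config$genes_per_mb * (isochores$length_bp / 1e6) *
      w[as.character(isochores$iso_class)]
    n_genes <- rpois(nrow(isochores), lambda)
    gene_rows <- rep(seq_len(nrow(isochores)), n_genes)
    glen <- pmax(round(rnorm(length(gene_rows), config$gene_length_mean,
                             config$gene_length_mean / 4)),
                 config$gene_length_min)
    glen <- pmin(glen, isochores$length_bp[gene_rows])
    gstart <- isochores$start[gene_rows] +
      floor(runif(length(gene_rows)) * (isochores$length_bp[gene_rows] - glen + 1))
    genes <- tibble(
      gene_id = sprintf("g%05d", seq_along(gene_rows)),
      chrom = isochores$chrom[gene_rows],
      start = gstart, end = gstart + glen,
      strand = sample(c("+", "-"), length(gene_rows), replace = TRUE),
      iso_class = isochores$iso_class[gene_rows]
    )
    genes$tss <- gene_tss(genes$start, genes$end, genes$strand)
    genes <- arrange(genes, .data$chrom, .data$start)
    genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
    list(layout = layout, isochores = isochores, genes = genes)
  })
}

# Replicate column names "t1:treatment", "c1:control", ...
replicate_columns <- function(n_rep) {
  c(sprintf("t%d:treatment", seq_len(n_rep)), sprintf("c%d:control", seq_len(n_rep)))
}

# NB draw that degrades to Poisson when dispersion is 0.
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate per-window methylation read counts
#'
#' Tiles each chromosome with consecutive non-overlapping windows, assigns
#' every window the isochore class containing its midpoint, plants
#' differential windows per class (fraction `meth_diff_fraction`, direction
#' hyper with probability `meth_hyper_prob`, treatment mean scaled by
#' `meth_effect_fold`) and draws negative-binomial counts around log-normal
#' window means scaled by per-replicate library factors.
#'
#' @param genome Output of [simulate_genome()].
#' @param config A [simulation_config()].
#' @return List with `counts` (window tibble `chrom, start, end` plus one
#'   column per replicate named `replicate:group`) and `truth`
#'   (`chrom, start, end, iso_class, is_diff, direction`).
#' @export
simulate_methylation <- function(genome, config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(stage_seed(config, "methylation"), {
    wb <- config$window_bp
    windows <- purrr::map_dfr(seq_len(nrow(genome$layout)), function(i) {
      L <- genome$layout$length_bp[i]
      starts <- seq(0, L - 1, by = wb)
      tibble(chrom = genome$layout$chrom[i], start = starts,
             end = pmin(starts + wb, L))
    })
    mid <- tibble(chrom = windows$chrom,
                  start = floor((windows$start + windows$end) / 2))
    mid$end <- mid$start + 1
    hit <- overlap_pairs(mid, genome$isochores)
    wclass <- factor(rep(NA_character_, nrow(windows)), levels = iso_classes())
    wclass[hit$query] <- genome$isochores$iso_class[hit$subject]
    diff_frac <- config$meth_diff_fraction[as.character(wclass)]
    diff_frac[is.na(diff_frac)] <- 0
    is_diff <- runif(nrow(windows)) < diff_frac
    hyper_p <- config$meth_hyper_prob[as.character(wclass)]
    direction <- ifelse(
      is_diff, ifelse(runif(nrow(windows)) < hyper_p, "hyper", "hypo"), NA
    )
    mu <- rlnorm(nrow(windows), config$window_mu_meanlog, config$window_mu_sdlog)
    fold <- rep(1, nrow(windows))
    fold[which(direction == "hyper")] <- config$meth_effect_fold
    fold[which(direction == "hypo")] <- 1 / config$meth_effect_fold
    n_rep <- config$replicates_per_group
    cols <- replicate_columns(n_rep)
    lib_factor <- pmax(rnorm(2 * n_rep, 1, config$library_size_cv), 0.2)
    counts <- windows
    for (j in seq_along(cols)) {
      mu_j <- if (j <= n_rep) mu * fold * lib_factor[j] else mu * lib_factor[j]
      counts[[cols[j]]] <- rcounts(nrow(windows), mu_j, config$nb_dispersion)
    }
    truth <- tibble(chrom = windows$chrom, start = windows$start,
                    end = windows$end, iso_class = wclass,
                    is_diff = is_diff, direction = direction)
    list(counts = counts, truth = truth)
  })
}

#' Simulate per-gene expression read counts
#'
#' Draws negative-binomial counts around log-normal per-gene means; the
#' treatment mean of each gene is multiplied by `exp(lfc)` where the planted
#' log fold change is normal with the class-specific mean `expr_lfc_mean` and
#' sd `expr_lfc_sd`.
#'
#' @inheritParams simulate_methylation
#' @return List with `counts` (first column `gene_id`, replicate columns
#'   named `replicate:group`) and `truth` (`gene_id, iso_class, lfc`).
#' @export
simulate_expression <- function(genome, config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(stage_seed(config, "expression"), {
    genes <- genome$genes
    mu <- rlnorm(nrow(genes), config$expr_mu_meanlog, config$expr_mu_sdlog)
    lfc <- rnorm(nrow(genes),
                 config$expr_lfc_mean[as.character(genes$iso_class)],
                 config$expr_lfc_sd)
    n_rep <- config$replicates_per_group
    cols <- replicate_columns(n_rep)
    lib_factor <- pmax(rnorm(2 * n_rep, 1, config$library_size_cv), 0.2)
    counts <- tibble(gene_id = genes$gene_id)
    for (j in seq_along(cols)) {
      mu_j <- if (j <= n_rep) mu * exp(lfc) * lib_factor[j] else mu * lib_factor[j]
      counts[[cols[j]]] <- rcounts(nrow(genes), mu_j, config$nb_dispersion)
    }
    truth <- tibble(gene_id = genes$gene_id, iso_class = genes$iso_class, lfc = lfc)
    list(counts = counts, truth = truth)
  })
}

#' Simulate GO associations and SNP positions
#'
#' Each configured GO term samples `go_term_size` genes without replacement
#' with probability proportional to the term's class weights, so a weight
#' vector concentrated on GC-rich classes yields a gene set overrepresented
#' there. SNP counts per isochore are Poisson with the class-specific density
#' and positions are uniform within the isochore.
#'
#' @inheritParams simulate_methylation
#' @return List with `go` (`gene_id, term_id`) and `snps`
#'   (`chrom, pos, trait`, 0-based positions, trait `synthetic_trait`).
#' @export
simulate_annotations <- function(genome, config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(stage_seed(config, "annotation"), {
    genes <- genome$genes
    go <- purrr::imap_dfr(config$go_terms, function(wt, term) {
      if (is.null(names(wt))) names(wt) <- iso_classes()
      p <- wt[as.character(genes$iso_class)]
      if (sum(p) == 0) abort(sprintf("GO term %s: all sampling weights are 0.", term))
      size <- min(config$go_term_size, sum(p > 0))
      tibble(gene_id = sample(genes$gene_id, size, prob = p), term_id = term)
    })
    iso <- genome$isochores
    n_snp <- rpois(nrow(iso),
                   config$snp_density_per_mb[as.character(iso$iso_class)] *
                     iso$length_bp / 1e6)
    rows <- rep(seq_len(nrow(iso)), n_snp)
    snps <- tibble(
      chrom = iso$chrom[rows],
      pos = iso$start[rows] + floor(runif(length(rows)) * iso$length_bp[rows]),
      trait = "synthetic_trait"
    )
    list(go = go, snps = snps)
  })
}

#' Simulate a complete study bundle
#'
#' Runs all generator stages off one master seed and returns every table the
#' pipeline consumes plus the ground truth used to validate recovery.
#'
#' @param config A [simulation_config()].
#' @return List of class `isobias_bundle`: `config, layout, isochores, genes,
#'   meth_counts, meth_truth, expr_counts, expr_truth, go, snps`.
#' @export
simulate_study <- function(config) {
  genome <- simulate_genome(config)
  meth <- simulate_methylation(genome, config)
  expr <- simulate_expression(genome, config)
  annot <- simulate_annotations(genome, config)
  structure(
    list(config = config, layout = genome$layout, isochores = genome$isochores,
         genes = genome$genes, meth_counts = meth$counts,
         meth_truth = meth$truth, expr_counts = expr$counts,
         expr_truth = expr$truth, go = annot$go, snps = annot$snps),
    class = "isobias_bundle"
  )
}

#' Write a study bundle to disk in the package's tabular formats
#'
#' @param bundle An [simulate_study()] bundle.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly. Files: `isochores.tsv`, `genes.bed`,
#'   `meth_counts.tsv`, `expr_counts.tsv`, `go.tsv`, `snps.tsv`,
#'   `layout.tsv`.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "isobias_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_isochores(bundle$isochores, file.path(dir, "isochores.tsv"))
  write_genes(bundle$genes, file.path(dir, "genes.bed"))
  meth <- bundle$meth_counts
  meth_out <- cbind(
    tibble(window = sprintf("%s:%d-%d", meth$chrom, meth$start, meth$end)),
    meth[, -(1:3)]
  )
  readr::write_tsv(meth_out, file.path(dir, "meth_counts.tsv"))
  write_counts(bundle$expr_counts, file.path(dir, "expr_counts.tsv"))
  write_go(bundle$go, file.path(dir, "go.tsv"))
  write_snps(bundle$snps, file.path(dir, "snps.tsv"))
  readr::write_tsv(bundle$layout, file.path(dir, "layout.tsv"))
  invisible(dir)
}
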