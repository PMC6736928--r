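#' Readers and writers for the package's tabular formats
#'
#' All readers convert source coordinates to the internal convention (0-based,
#' half-open) exactly once; all writers emit the documented source convention,
#' so `write_*()` followed by `read_*()` is the identity on canonical tables.
#'
#' Formats:
#' * Isochore map: 5-column TSV `chrom, start, end, iso_class, gc` with
#'   1-based inclusive coordinates (IsoFinder-style).
#' * Genes: BED6 (0-based half-open: `chrom, start, end, name, score, strand`)
#'   or GFF3 (1-based inclusive, `gene` features, `ID=` attribute).
#' * Counts: TSV, first column the feature id, remaining columns one per
#'   replicate with header `replicate:group`.
#' * DMRs: TSV `chrom, start, end, direction, p` (0-based half-open,
#'   direction `hyper`/`hypo`).
#' * SNPs: TSV `chrom, pos, trait` with 1-based positions.
#' * GO associations: TSV `gene_id, term_id`.
#'
#' @param path File path.
#' @name isobias-io
NULL

read_tsv_strict <- function(path, col_types) {
  out <- suppressWarnings(readr::read_tsv(path, col_types = col_types,
                                          progress = FALSE))
  probs <- suppressWarnings(readr::problems(out))
  if (nrow(probs) > 0) {
    # problems() reports 1-based file lines (header included)
    abort(sprintf(
      "Malformed row in %s: line %d, column %d (expected %s, got %s).",
      path, probs$row[1], probs$col[1], probs$expected[1], probs$actual[1]
    ))
  }
  out
}

#' @rdname isobias-io
#' @return `read_isochores()`: tibble `chrom, start, end, iso_class, gc,
#'   length_bp` (0-based half-open, `iso_class` a factor).
#' @export
read_isochores <- function(path) {
  x <- read_tsv_strict(path, readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), iso_class = readr::col_character(),
    gc = readr::col_double()
  ))
  x$start <- x$start - 1  # 1-based inclusive -> 0-based half-open
  x$iso_class <- factor(x$iso_class, levels = iso_classes())
  x$length_bp <- x$end - x$start
  validate_intervals(x, what = "isochore")
  x
}

#' @rdname isobias-io
#' @param isochores Isochore tibble as returned by [read_isochores()].
#' @export
write_isochores <- function(isochores, path) {
  out <- tibble(
    chrom = isochores$chrom, start = isochores$start + 1, end = isochores$end,
    iso_class = as.character(isochores$iso_class), gc = isochores$gc
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname isobias-io
#' @param format `"bed"` (BED6, 0-based half-open) or `"gff3"` (1-based
#'   inclusive; requires the rtracklayer package). `"auto"` picks by file
#'   extension.
#' @return `read_genes()`: tibble `gene_id, chrom, start, end, strand, tss`.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    x <- read_tsv_strict(path, readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), gene_id = readr::col_character(),
      score = readr::col_double(), strand = readr::col_character()
    ))
    genes <- tibble(gene_id = x$gene_id, chrom = x$chrom,
                    start = x$start, end = x$end, strand = x$strand)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("Reading GFF3 requires the rtracklayer package.")
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    genes <- tibble(
      gene_id = as.character(gr$ID),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,  # 1-based inclusive -> 0-based
      end = as.numeric(GenomicRanges::end(gr)),
      strand = as.character(GenomicRanges::strand(gr))
    )
  }
  validate_intervals(genes, what = "gene")
  genes$tss <- gene_tss(genes$start, genes$end, genes$strand)
  genes
}

#' @rdname isobias-io
#' @param genes Gene tibble as returned by [read_genes()].
#' @export
write_genes <- function(genes, path) {
  out <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
                gene_id = genes$gene_id, score = 0, strand = genes$strand)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname isobias-io
#' @return `read_counts()`: tibble whose first column is the feature id and
#'   whose remaining columns are replicate counts named `replicate:group`.
#' @export
read_counts <- function(path) {
  header <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE))
  spec <- c(list(readr::col_character()),
            rep(list(readr::col_double()), length(header) - 1))
  names(spec) <- header
  x <- read_tsv_strict(path, do.call(readr::cols, spec))
  bad <- !grepl(":", header[-1], fixed = TRUE)
  if (any(bad)) {
    abort(sprintf("Count column headers must be 'replicate:group'; bad: %s",
                  paste(header[-1][bad], collapse = ", ")))
  }
  x
}

#' @rdname isobias-io
#' @param counts Count tibble as returned by [read_counts()].
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Replicate-group design of a count table
#'
#' @param counts A count tibble whose replicate columns are named
#'   `replicate:group`.
#' @return Tibble `column, replicate, group`.
#' @export
count_groups <- function(counts) {
  cols <- names(counts)[-1]
  parts <- strsplit(cols, ":", fixed = TRUE)
  tibble(
    column = cols,
    replicate = vapply(parts, `[`, "", 1),
    group = vapply(parts, `[`, "", 2)
  )
}

#' @rdname isobias-io
#' @return `read_dmrs()`: tibble `chrom, start, end, direction, p` with
#'   `direction` a factor (`hyper`, `hypo`).
#' @export
read_dmrs <- function(path) {
  x <- read_tsv_strict(path, readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), direction = readr::col_character(),
    p = readr::col_double()
  ))
  if (!all(x$direction %in% c("hyper", "hypo"))) {
    abort("DMR direction must be 'hyper' or 'hypo'.")
  }
  x$direction <- factor(x$direction, levels = c("hyper", "hypo"))
  validate_intervals(x, what = "DMR")
  x
}

#' @rdname isobias-io
#' @param dmrs DMR tibble as returned by [read_dmrs()].
#' @export
write_dmrs <- function(dmrs, path) {
  out <- dplyr::select(dmrs, "chrom", "start", "end", "direction", "p")
  out$direction <- as.character(out$direction)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname isobias-io
#' @return `read_snps()`: tibble `chrom, pos, trait` with 0-based positions.
#' @export
read_snps <- function(path) {
  x <- read_tsv_strict(path, readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    trait = readr::col_character()
  ))
  x$pos <- x$pos - 1  # 1-based -> 0-based
  x
}

#' @rdname isobias-io
#' @param snps SNP tibble as returned by [read_snps()].
#' @export
write_snps <- function(snps, path) {
  out <- tibble(chrom = snps$chrom, pos = snps$pos + 1, trait = snps$trait)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname isobias-io
#' @return `read_go()`: tibble `gene_id, term_id`.
#' @export
read_go <- function(path) {
  read_tsv_strict(path, readr::cols(
    gene_id = readr::col_character(), term_id = readr::col_character()
  ))
}

#' @rdname isobias-io
#' @param go GO association tibble.
#' @export
write_go <- function(go, path) {
  readr::write_tsv(go[, c("gene_id", "term_id")], path)
  invisible(path)
}
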