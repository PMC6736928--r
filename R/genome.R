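#' Isochore class levels
#'
#' The five isochore families ordered from the most AT-enriched (`L1`) to the
#' most GC-enriched (`H3`).
#'
#' @return Character vector of the five class labels.
#' @export
iso_classes <- function() c("L1", "L2", "H1", "H2", "H3")

#' Default GC-fraction boundaries between isochore classes
#'
#' The classical five-family scheme: L1 < 37% GC, L2 37-41%, H1 41-46%,
#' H2 46-53%, H3 >= 53%. Boundaries are half-open: a GC fraction exactly at a
#' boundary belongs to the higher class.
#'
#' @return Numeric vector of four ascending GC fractions.
#' @export
default_gc_boundaries <- function() c(0.37, 0.41, 0.46, 0.53)

#' Classify GC fractions into isochore classes
#'
#' @param gc Numeric vector of GC fractions in \[0, 1\].
#' @param boundaries Four strictly ascending GC fractions in (0, 1) separating
#'   the five classes; see [default_gc_boundaries()].
#' @return Factor with levels `L1, L2, H1, H2, H3`, same length as `gc`.
#' @examples
#' classify_isochores(c(0.30, 0.37, 0.55))
#' @export
classify_isochores <- function(gc, boundaries = default_gc_boundaries()) {
  if (length(boundaries) != 4 || any(diff(boundaries) <= 0) ||
      any(boundaries <= 0) || any(boundaries >= 1)) {
    abort("`boundaries` must be 4 strictly ascending fractions in (0, 1).")
  }
  bad <- !is.na(gc) & (gc < 0 | gc > 1)
  if (any(bad)) {
    abort(sprintf("GC fraction outside [0, 1]: %s", paste(gc[bad], collapse = ", ")))
  }
  idx <- findInterval(gc, boundaries) + 1L
  factor(iso_classes()[idx], levels = iso_classes())
}

#' Build a genome layout
#'
#' A genome layout is the ordered table of chromosome names and lengths that
#' anchors every interval in the package (internal coordinates are 0-based,
#' half-open).
#'
#' @param chrom Character vector of unique chromosome names (order is kept).
#' @param length_bp Positive integer lengths in base pairs.
#' @return A tibble with columns `chrom`, `length_bp`.
#' @export
genome_layout <- function(chrom, length_bp) {
  if (length(chrom) != length(length_bp)) abort("`chrom` and `length_bp` lengths differ.")
  if (anyDuplicated(chrom)) abort("Chromosome names must be unique.")
  if (any(length_bp <= 0)) abort("Chromosome lengths must be > 0.")
  tibble(chrom = as.character(chrom), length_bp = as.numeric(length_bp))
}

#' GRCm38 chromosome layout
#'
#' Chromosome lengths for the mouse GRCm38 primary assembly: the 19 autosomes,
#' X, Y and the mitochondrial sequence (22 sequences in total). This is the
#' chromosome set under which the genome-wide count of consecutive
#' non-overlapping 100-bp windows reproduces the analytic minimum of the
#' mDMR/DMR ratio curve, 22 / 27,255,386 = 8.07e-07 (see [mdmr_floor()]).
#'
#' @return A genome layout tibble (see [genome_layout()]).
#' @export
grcm38_layout <- function() {
  genome_layout(
    chrom = c(paste0("chr", 1:19), "chrX", "chrY", "chrM"),
    length_bp = c(
      195471971, 182113224, 160039680, 156508116, 151834684, 149736546,
      145441459, 129401213, 124595110, 130694993, 122082543, 120129022,
      120421639, 124902244, 104043685, 98207768, 94987271, 90702639,
      61431566, 171031299, 91744698, 16299
    )
  )
}

# Validate a tibble of 0-based half-open intervals (chrom/start/end),
# optionally against a layout. Returns the tibble invisibly.
validate_intervals <- function(x, layout = NULL, what = "interval") {
  for (col in c("chrom", "start", "end")) {
    if (!col %in% names(x)) abort(sprintf("%s table lacks column `%s`.", what, col))
  }
  bad <- x$start < 0 | x$start >= x$end
  if (any(bad)) {
    abort(sprintf("%s rows violate 0 <= start < end (first bad row: %d).",
                  what, which(bad)[1]))
  }
  if (!is.null(layout)) {
    len <- layout$length_bp[match(x$chrom, layout$chrom)]
    over <- !is.na(len) & x$end > len
    if (any(over)) {
      abort(sprintf("%s rows extend past chromosome end (first bad row: %d).",
                    what, which(over)[1]))
    }
  }
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based inclusive internally).
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

# All (query row, subject row) pairs sharing >= 1 bp, as a tibble.
overlap_pairs <- function(queries, subjects) {
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    as_granges0(queries), as_granges0(subjects), minoverlap = 1L
  ))
  tibble(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits)
  )
}

#' Isochore classes overlapped by query intervals
#'
#' A query interval is a member of every isochore class it overlaps by at
#' least one base; a query overlapping no isochore maps to an empty class set.
#' Queries on chromosomes absent from the isochore map are reported (message)
#' and map to the empty set.
#'
#' @param queries Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param isochores Isochore tibble with `chrom`, `start`, `end`, `iso_class`;
#'   isochores must not overlap one another within a chromosome.
#' @return `queries` with a list-column `iso_classes` (character vector of
#'   overlapped classes, possibly empty).
#' @export
overlap_iso_classes <- function(queries, isochores) {
  validate_intervals(queries, what = "query")
  validate_intervals(isochores, what = "isochore")
  missing_chrom <- setdiff(unique(queries$chrom), unique(isochores$chrom))
  if (length(missing_chrom) > 0) {
    inform(sprintf("Chromosomes absent from isochore map: %s",
                   paste(missing_chrom, collapse = ", ")))
  }
  hits <- overlap_pairs(queries, isochores)
  cls <- as.character(isochores$iso_class)[hits$subject]
  sets <- split(cls, factor(hits$query, levels = seq_len(nrow(queries))))
  queries$iso_classes <- lapply(sets, function(v) unique(v))
  queries
}

#' Strand-aware TSS windows
#'
#' Builds the promoter-proximal window around each gene's transcription start
#' site: `upstream` bases upstream through `downstream` bases downstream,
#' where "upstream" follows the gene's strand. Plus-strand genes get
#' `[tss - upstream, tss + downstream)`; minus-strand genes the mirrored
#' `[tss - downstream + 1, tss + upstream + 1)`. Windows have width
#' `upstream + downstream` before clipping at chromosome bounds.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `strand` (`"+"`/`"-"`) and
#'   `tss` (0-based position).
#' @param upstream,downstream Window extent in bp (defaults 1500/500, the
#'   promoter rule used to define gene subset I).
#' @param layout Optional genome layout used to clip windows at `[0, length)`.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`.
#' @export
tss_windows <- function(genes, upstream = 1500, downstream = 500, layout = NULL) {
  if (!all(genes$strand %in% c("+", "-"))) abort("Gene strand must be '+' or '-'.")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1)
  start <- pmax(start, 0)
  if (!is.null(layout)) {
    len <- layout$length_bp[match(genes$chrom, layout$chrom)]
    end <- ifelse(is.na(len), end, pmin(end, len))
  }
  tibble(gene_id = genes$gene_id, chrom = genes$chrom, start = start, end = end)
}

# TSS from interval + strand (start for +, end - 1 for -).
gene_tss <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1)
}
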