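#' Build iso-directional differentially methylated blocks (isoDMBs)
#'
#' An isoDMB is a genomic region punctuated by same-direction DMRs: a maximal
#' run of at least `min_dmrs` DMRs with the same direction of change,
#' uninterrupted by any opposite-direction DMR and, when `max_gap` is finite,
#' by inter-DMR gaps larger than `max_gap`. The block interval spans from the
#' start of its first DMR to the end of its last, so blocks of one tissue
#' never overlap and never contain an opposite-direction DMR.
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param min_dmrs Minimum number of member DMRs per block (default 2: a
#'   single DMR is not a region "punctuated by" DMRs).
#' @param max_gap Maximum allowed gap in bp between consecutive member DMRs
#'   (default `Inf`, no cap).
#' @return Tibble `chrom, start, end, direction, n_dmrs`.
#' @export
build_isodmbs <- function(dmrs, min_dmrs = 2, max_gap = Inf) {
  if (nrow(dmrs) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  direction = factor(character(), levels = c("hyper", "hypo")),
                  n_dmrs = integer()))
  }
  d <- arrange(dmrs, .data$chrom, .data$start)
  gap <- d$start - lag(d$end, default = -Inf)
  new_run <- d$chrom != lag(d$chrom, default = "") |
    as.character(d$direction) != lag(as.character(d$direction), default = "") |
    gap > max_gap
  run <- cumsum(new_run)
  blocks <- d %>%
    group_by(run = run) %>%
    summarise(chrom = first(.data$chrom), start = first(.data$start),
              end = last(.data$end), direction = first(.data$direction),
              n_dmrs = n(), .groups = "drop") %>%
    select(-"run")
  filter(blocks, .data$n_dmrs >= min_dmrs)
}

#' Genes located within isoDMBs (gene subset III)
#'
#' Assigns a gene to a block's subset when the gene interval overlaps the
#' block by at least one base (`mode = "overlap"`, the package-wide overlap
#' rule) or only when it is fully contained (`mode = "within"`). Hyper- and
#' hypo-block memberships are reported separately.
#'
#' @param genes Gene tibble (`gene_id, chrom, start, end`).
#' @param blocks isoDMB tibble from [build_isodmbs()].
#' @param mode Membership rule, `"overlap"` (default) or `"within"`.
#' @return Tibble `gene_id, direction` (one row per gene x block-direction).
#' @export
genes_in_isodmbs <- function(genes, blocks, mode = c("overlap", "within")) {
  mode <- match.arg(mode)
  if (nrow(blocks) == 0 || nrow(genes) == 0) {
    return(tibble(gene_id = character(),
                  direction = factor(character(), levels = c("hyper", "hypo"))))
  }
  hits <- overlap_pairs(genes, blocks)
  if (mode == "within") {
    inside <- genes$start[hits$query] >= blocks$start[hits$subject] &
      genes$end[hits$query] <= blocks$end[hits$subject]
    hits <- hits[inside, ]
  }
  distinct(tibble(gene_id = genes$gene_id[hits$query],
                  direction = blocks$direction[hits$subject]))
}
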