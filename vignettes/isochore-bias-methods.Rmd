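---
title: "Isochore-stratified methylation and expression bias: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isochore-stratified methylation and expression bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobias)
```

## The scientific problem

Environmental exposures can shift DNA methylation and gene expression not
gene-by-gene but *regionally*, in a way that tracks the large-scale base
composition of the genome. Mammalian genomes are mosaics of isochores — long
stretches of relatively uniform GC content, conventionally assorted into five
families from the most AT-rich (L1) to the most GC-rich (H3). `isobias`
implements a complete, testable pipeline for asking whether differential
methylation and concerted expression changes are biased with respect to this
mosaic: window-based DMR calling, data-driven significance-threshold
selection, regional block construction, isochore-stratified enrichment
statistics with tag-permutation nulls, and a Monte-Carlo–Wilcoxon test of
subset-level expression bias.

Everything operates on plain tables (tibbles in, tibbles out), so the stages
compose with ordinary tidyverse verbs. Internal coordinates are 0-based,
half-open; every reader converts from its documented source convention
exactly once, and "overlap" always means an intersection of at least one
base.

## Per-window testing and DMR calling

Methylation enrichment counts (e.g. MBD-seq) are summarized over consecutive,
non-overlapping 100-bp windows. `test_windows()` pools counts within each
group and applies a two-sided exact binomial test of the treatment share of
pooled reads against the treatment share of total library size; the direction
of change is the sign of the difference in CPM-normalized group means. A
window with equal normalized means is tied (direction 0) and can never become
a DMR, and all-zero windows get p = 1.

The engine is deliberately pluggable: every downstream statistic consumes
only `(p, direction)` per window, so a replicate-aware count model can be
substituted without touching the rest of the pipeline. The pooled binomial
ignores biological replicate variance and is therefore anti-conservative as a
*marginal* test under overdispersion; this does not bias the stratified
statistics, whose permutation nulls only require that window calls be
exchangeable with respect to isochore labels.

`call_dmrs()` keeps windows with `p <= threshold` and a direction
(hypermethylated = higher coverage in treatment). `merge_adjacent_dmrs()`
fuses maximal runs of contiguous (zero-gap), same-direction DMR windows into
mDMRs.

## Choosing the threshold: the mDMR/DMR curve

Rather than adopting a fixed cutoff blindly, the ratio of merged to unmerged
DMR counts is tracked across a grid of thresholds (`mdmr_curve()`; default 46
log-spaced values between 1e-5 and 1 — the grid density is a package choice,
as only the count and range of the published grid are public). A ratio near 1
means newly admitted DMRs are isolated; a falling ratio means they accrete
onto existing regions. The analytic floor of the ratio is
`n_chromosomes / n_windows` — attained when every window of every chromosome
is a same-direction DMR. For the GRCm38 sequence set shipped in
`grcm38_layout()` (19 autosomes, X, Y and MT; the mitochondrial sequence is
required to reproduce the published constant) the floor is
`r signif(mdmr_floor(grcm38_layout()), 3)`.

`select_p_threshold()` returns the smallest grid point from which every
tissue's ratio declines monotonically (within a configurable tolerance,
default 0) — the point past which relaxation only broadens known regions.
The conventional `p = 0.001` is the default override in `run_pipeline()`.

Recurrence between two tissues is quantified by `rdmr_fraction()`, a
direction-aware Jaccard index on window keys: a shared window with opposite
directions counts in the union only.

## isoDMBs

`build_isodmbs()` identifies iso-directional differentially methylated
blocks: maximal runs of at least `min_dmrs` same-direction DMRs,
uninterrupted by opposite-direction DMRs and (optionally) by gaps larger than
`max_gap`. The published construction leaves the minimum run length and gap
cap unstated, so the defaults here — `min_dmrs = 2` (a single DMR is not a
region "punctuated by" DMRs) and `max_gap = Inf` — are explicit, configurable
stand-ins. Gene membership in a block (`genes_in_isodmbs()`) follows the
package-wide one-base overlap rule, with strict containment available via
`mode = "within"`.

## Isochore-stratified statistics and tag permutation

Four statistics share one permutation engine:

* hyper/hypo DMR ratio, `(u/d) / (U/D)`;
* DMR enrichment, `(x/X) / (l/L)` with `l` the cumulative class length;
* GO-term gene enrichment, `(x/n) / (X/N)`;
* GWAS-SNP enrichment, `(x/X) / (l/L)` with SNPs mapped as points.

An interval (DMR or gene) overlapping several classes belongs to every class
it touches but is counted once in the genome-wide denominators; a SNP maps to
the single isochore containing it. Classes with a zero denominator (`d = 0`,
`l = 0`, `n = 0`) are reported as undefined rather than dropped silently.

The null rearranges the isochore **class tags** across isochore records —
lengths and overlap structure stay put, so each draw is a relabeling, never a
resampling — and recomputes the statistic. The conventional null size is
10,000 draws (the `mcw_test()` default); the four bias statistics return the
observed value alone unless `n_perm` is given, and `run_pipeline()` defaults
to 1,000 draws for interactive use — raise it for final reports. Empirical
`p_upper`/`p_lower` are
tail fractions with ties counted in both tails, significance is declared when
either is below 0.05, and no multiple-testing correction is applied across
the 5 classes × statistics grid (raw empirical p-values with a fixed cutoff;
correction is left to the caller). Each statistic within a run draws its
permutations from its own derived seed, so adding or removing one statistic
never changes another's null.

For the figures, `percentile_band()` forms
`(log10(observed/p5), log10(observed/p95))` from the 5th/95th null
percentiles (linear interpolation between order statistics, `quantile`
type 7): a band entirely above zero is significantly high, entirely below is
significantly low. Base-10 logs are used; the base is configurable.

## The Monte-Carlo–Wilcoxon GEBI test

Expression counts pass the expressed-gene filter (`filter_expressed()`:
count > 0 in at least two replicates of each group), are normalized to CPM
with library sizes taken as column sums of the filtered matrix (the published
computation names CPM but not the library-size definition, so the simplest
one is used), and are summarized per gene and group by the mean `M` and the
coefficient of variation `CV` (`gene_deltas()`). For a chosen difference
(`delta_m` or `delta_cv`), `signed_ranks()` drops zero differences (the
standard Wilcoxon convention; the source is silent on zeros), ranks the rest
by absolute value with average ranks on ties, and signs the ranks.

The gene-expression bias index of a subset (`gebi()`) is the subset's
signed-rank sum divided by the maximum it could attain — the sum of the `k`
largest realized rank magnitudes, which keeps the index in [-1, 1] under
ties. `mcw_test()` shuffles the signed-rank vector across the gene universe
(one shuffle per draw serving all subsets, preserving their correlation under
the null) and reports the same empirical-p machinery as above. The mean- and
CV-based indices (mGEBI, cvGEBI) are the same code path parameterized by the
ranked column.

Gene subsets tied to methylation come from `dmr_gene_subsets()`: subset I
(a DMR within 1,500 bp upstream or 500 bp downstream of the TSS,
strand-aware), subset II (genes overlapping a DMR, plus the nearest gene on
each side of every intergenic DMR — the flanking rule has no published
distance cap, so `flank_max` defaults to infinity and is configurable), and
subset III (genes in isoDMBs), each split by direction.

## Power analysis

`required_sample_size()` searches the smallest per-group `n` whose
two-sample t-test power, computed from the noncentral t distribution
(`df = 2n - 2`, noncentrality `d * sqrt(n/2)`), reaches the target. With
`d = 3.92`, two-sided `alpha = 0.05` and target power 0.95 the minimum is
`n = 4` (power 0.94 at n = 3, 0.995 at n = 4); the two-sided form is adopted
because it reproduces that published bound.

## The synthetic-data generator

`simulation_config()` + `simulate_study()` produce a complete study bundle
with known ground truth: an isochore mosaic tiling each chromosome (truncated
normal lengths, i.i.d. class draws, class-consistent GC values), genes placed
wholly inside isochores so each has an unambiguous true class, 100-bp
methylation windows with log-normal baseline means (coverage heterogeneity)
and negative-binomial noise, per-gene expression counts, and class-biased GO
terms and SNP densities. Defaults encode the emulated study conditions:
5 biological replicates per group, overdispersed counts
(dispersion 0.05, a typical bulk-tissue value), a hypermethylation bias
planted in H3 (hyper probability 0.9) and a hypomethylation bias in L1 (0.1)
over a 20% differential-window fraction at 4-fold effect, and expression
shifts of ±0.5 natural-log units (sd 0.2) in H3/L1. Where the emulated study
reports no value (baseline coverage, library-size CV, gene density), a single
realistic choice was fixed up front and documented in the function's help.

One master seed drives fixed per-stage substreams, so regenerating one table
never perturbs the others and a bundle is byte-identical across runs. The
generator deliberately omits read-level simulation, CpG-density–dependent
capture bias, sex chromosomes, replicate pooling (pooling only rescales
dispersion) and litter structure — so passing tests demonstrate that the
*statistics* behave as designed, not that the generator reproduces every
property of real MBD-seq/RNA-seq data.

## Numerical choices and degenerate inputs

* GC boundaries default to 37/41/46/53% (the classical five-family scheme;
  the cutoffs are configurable because published isochore maps vary); bins
  are half-open, so a GC fraction exactly at a boundary takes the higher
  class.
* Minus-strand TSS windows mirror the plus-strand convention used by
  `GenomicRanges::promoters()`, keeping the width `upstream + downstream`.
* Permutation p-values use an absolute tie tolerance of `1e-12 ·
  max(1, |observed|)` so that exact ties of floating-point sums register in
  both tails.
* Empty DMR sets, classes with zero denominators, empty gene subsets and
  SNPs outside the isochore map are all reported (NA / message / warning)
  rather than silently dropped or turned into zeros.
* Test-suite and example problem sizes (2-Mb genomes, 20,000 windows,
  ~2,000 genes, 400–4,000 permutations) were chosen as the smallest designs
  at which the planted effects are comfortably detectable; publication
  analyses should use the 10,000-permutation default.

## Known limitations

The default window test is marginal (no replicate-level variance model); the
flanking rule of subset II is a nearest-gene stand-in for an unstated
published definition; isoDMB construction parameters are likewise explicit
stand-ins; and the permutation nulls treat isochores as exchangeable units,
ignoring any spatial autocorrelation of class labels along chromosomes.
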