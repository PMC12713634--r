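---
title: "Methods: TSS-proximal binding enrichment and its validation"
author: "tssenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS-proximal binding enrichment and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssenrich)
```

This vignette documents the models and procedures the package
implements, the conventions and parameters that matter, the design
choices that were genuinely open, and what the synthetic-data validation
does and does not establish.

## The question and the pipeline

Given a transcription factor's ChIP-seq tag alignments and an RNA-seq
differential-expression analysis of a perturbation of that factor, the
pipeline asks whether genes that respond transcriptionally are
preferentially *bound*: whether the frequency of a binding site within a
fixed distance of the transcription start site (TSS) is higher among
up- or down-regulated genes than among expressed-but-unchanged control
genes. The answer is a set of per-group binding frequencies and pairwise
two-proportion Z-tests.

## Coordinates

All interval data are held in `GRanges` (1-based, closed — the
Bioconductor convention), which supplies the interval algebra
(`reduce`, `findOverlaps`). BED files are read and written in BED's
native 0-based half-open convention, converted only at the file
boundary; GTF input (1-based inclusive) is converted on read by
`rtracklayer`. Keeping a single internal convention and converting at
I/O eliminates off-by-one drift; all documentation of file formats is in
BED coordinates, all in-memory positions are `GRanges` positions.

## Peak calling

The caller is a deliberately plain threshold rule — no background model,
local lambda, or input subtraction — so that its behaviour is exactly
auditable:

* **Grid.** Bins of `bin_size` (default 1000 bp) starting every `step`
  (default 500 bp) from coordinate 0 of each chromosome, the final bins
  truncated at the chromosome end. The anchor at 0 is a reproducibility
  choice; truncated terminal bins are counted like any other so no base
  is excluded.
* **Counting.** Default mode `five_prime_start` assigns a tag to every
  bin containing its 5′ position (plus strand: start; minus strand: last
  base; unstranded: start). This makes each tag contribute to exactly
  the bins covering one base — with `step` dividing `bin_size`, every
  interior tag is counted in exactly `bin_size/step` bins, an exact
  conservation law the tests assert. The alternative `any_overlap`
  counts a tag in every bin it touches by ≥ 1 bp, as an intersect-based
  workflow would, at the cost of smearing each tag across its full
  width.
* **Threshold and merge.** Bins with tag count strictly greater than
  `threshold` (default 500) are selected — strict because the rule is
  "more than"; a flag flips to ≥ — and merged. Book-ended bins merge by
  default (consecutive passing bins on the grid abut exactly;
  `bedtools merge` behaves the same); `book_ended = FALSE` gives
  strict-overlap merging for sensitivity analysis. The absolute
  threshold is library-size dependent; the summary reports total and
  passing bin counts so users can judge it against their own depth.
* **Replicates and duplicates.** Multiple tag files are pooled before
  counting. Duplicate tags are kept by default (multiset semantics); a
  `dedup` flag removes identical intervals for users who deduplicate.

## Gene groups

`classify_genes()` partitions a DESeq2-style table into `up`
(padj < 0.05 and log2FC > 0), `down` (padj < 0.05 and log2FC < 0),
`unchanged` (not significant and baseMean strictly > 1), and `excluded`
(the remainder, chiefly unexpressed genes). The significance column is
`padj`, not raw p, and genes with missing padj — DESeq2's independent
filtering — are treated as not significant and routed by baseMean,
matching DESeq2's own reading of filtered genes. All three cutoffs are
arguments; the defaults are stated here once and used everywhere. The
baseMean cutoff keeps the control group comparable to the responsive
groups: genes with essentially no expression cannot respond and would
dilute the control frequency.

## TSS windows and overlap

The TSS is the 5′-most annotated base (strand mandatory). Windows are
symmetric, `±flank` around the TSS base (width `2*flank + 1` away from
chromosome ends), clipped half-open at the bounds. Overlapping windows
are merged **per gene** only: a gene with alternative TSSs closer than
`2*flank` contributes one merged window, so the downstream frequencies
count genes, not windows. Merging across genes would destroy the
gene-level denominators the group comparison needs, so it is not done.
Overlap with a peak requires ≥ 1 bp; abutting intervals do not count
(standard intersect semantics). Enlarging the flank can only add
overlaps, a monotonicity the tests check.

## The enrichment test

Group frequencies are compared with the pooled two-proportion Z-test
(two-sided by default). The comparisons reported are up vs unchanged,
down vs unchanged, and up vs down. Raw p-values are reported — three
tests, and the primary claim concerns a single pre-specified comparison
(up vs unchanged) — with a Bonferroni flag for users who prefer
correction. A one-sided option exists because the substantive hypothesis
("up-regulated genes are the most frequently bound") is directional.
When the pooled proportion is 0 or 1 the variance estimate vanishes; the
test returns z = 0, p = 1 flagged `degenerate` rather than dividing by
zero. A permutation cross-check and `prop.test`'s uncorrected chi-square
(which equals z²) back the implementation in the tests.

Two small utilities round out the statistics: `welch_t_test()` (Welch
statistic with Satterthwaite degrees of freedom, pooled-variance Student
variant by flag) for comparing replicate measurements, and
`qpcr_zscore()`, which converts Ct values to relative expression
`2^-(Ct_gene - Ct_ref)` against a single reference gene per sample and
standardizes each gene across samples to mean 0, SD 1 (constant genes
are flagged, not divided). Amplification-efficiency correction is out of
scope.

## The synthetic-data generator

The generator emulates the statistical structure the integration
analysis assumes; its defaults are the study conditions under which the
package validates itself:

* genome: 3 chromosomes × 3 Mb;
* genes: 60 up, 60 down, 60 unchanged, 30 excluded, placed on a slot
  grid with spacing `2*flank_used + guard` (defaults 10000 and 5000 bp),
  random strands, lengths uniform on 1–10 kb;
* DE table: up genes get padj ~ U(0, 0.04) and log2FC from N(2, 0.5)
  truncated above 0.5, down genes the mirror image, unchanged genes
  padj ~ U(0.2, 1) with baseMean > 1, excluded genes baseMean ≤ 1 — so
  `classify_genes()` at its defaults recovers the labels exactly, by
  construction;
* binding: each gene receives a planted site with probability 0.6 (up)
  or 0.1 (down, unchanged, a realistic non-zero background binding
  rate); the site centre is the TSS plus N(0, 2000 bp) noise clipped
  into the flank window; 1000 tags (twice the caller threshold) are
  emitted with 5′ positions N(centre, 50 bp) — the 5′ position is the
  planted quantity, matching the caller's default counting mode;
* background: uniform tags at 1 per kb (Poisson), so the expected
  background count per 1000 bp bin is 1, far below threshold/2; the
  validation formula `background_tag_rate * bin_size / 1000 <
  threshold / 2` is enforced at configuration time.

The slot spacing guarantees that TSS windows of different genes are
disjoint and — because the guard (5 kb) exceeds the maximal extent of a
planted peak beyond its window (tag cloud ≈ ±300 bp plus one bin width
each side) — that a peak planted at one gene cannot reach a neighbour's
window. Overlap flags therefore equal the planted binding indicators,
which is what makes truth evaluation unambiguous. All randomness flows
from one master seed; each stage (genes, DE table, tags) draws from a
fixed offset of it, so the full run and each stage separately are
deterministic, and emitted files are byte-identical across runs.

### What the simulation does and does not show

It exercises every pipeline stage against known truth: interval
arithmetic, counting, thresholding, classification, window overlap and
the test's calibration. It does **not** emulate real ChIP-seq:
no mappability or GC bias, no fragment-size shift between strands, no
duplicate structure, no spatially varying background, no multi-site
genes, and the DE table is simulated at the results level rather than
from counts. Passing tests therefore demonstrate correctness of the
computations and calibration of the statistics under clean conditions —
not robustness to the biases of real libraries, which users should judge
with the usual ChIP-seq QC.

## Validation design and problem sizes

The test suite validates at three levels, with sizes chosen to keep a
full run in minutes:

* **Oracle equivalence.** On 100 seeded random instances with ≤ 12 kb
  genomes, the peak caller and the window-overlap flags are compared,
  interval for interval, against brute-force oracles written
  independently in plain data frames: nested-loop tag counting, per-base
  boolean occupancy for unions and intersections.
* **Planted-truth recovery.** 100 seeded runs of a compact study
  (2 × 0.5 Mb genome, 15 genes per group, 1 kb flank, default tag and
  background rates) must recover every planted site with recall and
  precision 1, and the DE labels exactly.
* **Statistical calibration.** The up-vs-unchanged test's type-I error
  is estimated from 1000 full-pipeline replicates under equal binding
  probabilities (0.1 everywhere) on a compact genome (2 × 1 Mb, 1 kb
  flank, default group sizes), and must lie in [0.035, 0.065] at
  α = 0.05; the exact binomial-enumeration value for n = 60 per group
  and p = 0.1 is 0.0505, so the band allows ordinary Monte-Carlo
  fluctuation. Power under the default planted effect (0.6 vs 0.1,
  60 genes per group) is estimated from 200 replicates and must exceed
  0.9 (the asymptotic value is ≈ 1). The compact genomes change only
  the genome size and flank, not the binding probabilities, group
  sizes, tag rates or caller parameters, and — because overlap flags
  equal binding indicators under the spacing guarantee — leave the
  test's operating characteristics unchanged.
* **Directional finding.** Across 20 seeded runs at full defaults, the
  up group's binding frequency must be the strict maximum of the three
  groups at both the 10 kb and the 1 kb flank, and the up-vs-unchanged
  test must reject in at least 18 of 20 runs.

## Numerical and degenerate-input choices

* Threshold comparisons: strict (`>`) for both the tag-count threshold
  and the baseMean cutoff, because both rules are "greater than"; flags
  provide the non-strict variants.
* Empty inputs: empty tag files give zero counts everywhere and an
  empty peak set; an empty DE table gives four empty groups; a group
  with no annotated genes gets an `NA` proportion and `NA` tests, not an
  error.
* Zero-variance cases: the Z-test returns z = 0, p = 1 with a
  `degenerate` flag when the pooled proportion is 0 or 1; qPCR rows with
  constant relative expression are returned as `NA` and flagged.
* Ties and ordering: chromosome order is the layout's declared order
  everywhere (never lexicographic), so output is locale-independent;
  classification is invariant to row order.

## Known limitations

The caller's absolute tag threshold does not adapt to sequencing depth;
the enrichment makes no correction for gene length, promoter CpG
content or mappability; peaks are attributed to genes only through
fixed windows (no nearest-gene assignment or distance weighting); and
the two-proportion Z-test treats genes as independent Bernoulli trials,
which ignores spatial clustering of genes sharing a regulatory
neighbourhood. These are properties of the method itself, kept
deliberately simple; the package's contribution is to make every step
of it explicit, seeded and testable.
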