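# tssenrich

Integration of transcription-factor ChIP-seq binding with RNA-seq
differential expression, for regulatory-genomics analyses that ask a
simple question: **are the genes whose expression responds to a factor
also the genes the factor binds near?**

The package is aimed at analysts who have (i) aligned ChIP-seq tags for a
factor (BED intervals), (ii) a DESeq2-style differential-expression
results table, and (iii) a stranded gene annotation, and who want a
transparent, fully testable pipeline rather than a black box.

## The method

1. **Peak calling by bin thresholding.** Each chromosome is partitioned
   into overlapping fixed-width bins (default 1000 bp, sliding by 500 bp,
   anchored at position 0). Tags are counted per bin — by default a tag is
   assigned to every bin containing its 5′ position — and bins with more
   than a fixed tag count (default > 500, strict) are merged, overlapping
   and book-ended alike, into maximal disjoint peaks.
2. **Gene stratification.** A DESeq2 results table is partitioned into
   up-regulated (padj < 0.05, log2FC > 0), down-regulated (padj < 0.05,
   log2FC < 0), and unchanged genes; the unchanged (control) group keeps
   only expressed genes with baseMean > 1, the rest are excluded.
3. **TSS windows.** Strand-aware transcription start sites are extracted
   from the annotation (plus strand: gene start; minus strand: gene end),
   and symmetric windows of ±*flank* bp (typically 10 kb and 1 kb) are
   built around them, clipped at chromosome bounds, with a gene's
   overlapping alternative-TSS windows merged so each gene counts once.
4. **Enrichment.** For each group, the fraction of genes whose window
   intersects a peak by ≥ 1 bp is computed, and groups are compared with
   the pooled two-proportion Z-test

   $$z = \frac{\hat p_1 - \hat p_2}{\sqrt{\hat p(1-\hat p)\left(\tfrac{1}{n_1}+\tfrac{1}{n_2}\right)}},\qquad \hat p = \frac{x_1+x_2}{n_1+n_2}.$$

A seeded synthetic-data generator produces a toy genome, annotation,
DE table and tag set with binding sites planted preferentially near
up-regulated genes' TSSs, together with a machine-readable truth record,
so every stage of the pipeline is verifiable without any external data.
Utilities used alongside such analyses — Welch's t-test and qPCR
ΔCt Z-score normalization against a reference gene — are included.

## Worked example

```r
library(tssenrich)

cfg <- simulation_config(seed = 1)          # defaults: 3 x 3 Mb genome,
res <- run_full_simulation(cfg,             # 60 genes/group, p_bind
                           flanks = c(10000, 1000))  # 0.6/0.1/0.1
res
```

```
Synthetic integration-analysis run (seed 1)
  tags: 59115  peaks: 50  planted-site recall: 1  precision: 1

[flank_10000]
TSS-window peak-overlap enrichment
     group n_genes n_overlapping proportion
        up      60            34  0.5666667
      down      60            10  0.1666667
 unchanged      60             6  0.1000000

Pairwise two-proportion Z-tests (two.sided):
        comparison        z      p_value degenerate
   up_vs_unchanged 5.422177 5.887764e-08      FALSE
 down_vs_unchanged 1.074172 2.827455e-01      FALSE
        up_vs_down 4.546411 5.456833e-06      FALSE
```

Reading this: all 50 called peaks contain a planted site and every
planted site is recovered (recall = precision = 1); 56.7% of up-regulated
genes have a peak within 10 kb of their TSS versus 10% of unchanged
genes, and the pooled Z-test rejects equality decisively (z = 5.42,
p ≈ 6e-8) — the planted enrichment of binding near up-regulated genes is
detected. The same run at ±1 kb gives proportions 0.267/0.100/0.067 with
z = 2.94 (p = 0.0033): the signal survives the narrower promoter window.

The same analysis runs from files (BED tags, chrom.sizes, BED6/GTF
annotation, DESeq2 TSV) via `run_peak_calling()`, `read_deg_table()` +
`classify_genes()`, `build_windows()` + `gene_overlaps_peaks()` and
`run_enrichment()`, or from a shell through the thin CLI wrapper:

```sh
tssenrich=$(Rscript -e 'cat(system.file("scripts/tssenrich", package="tssenrich"))')
Rscript $tssenrich simulate  --seed 7 --outdir sim
Rscript $tssenrich callpeaks --tags sim/tags.bed --genome sim/genome.chrom.sizes --out peaks.bed
Rscript $tssenrich enrich    --peaks peaks.bed --annotation sim/genes.bed \
        --genome sim/genome.chrom.sizes --deg sim/deg.tsv --flank 10000 --out report.tsv
```

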