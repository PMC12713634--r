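#' Extract transcription start sites from a gene annotation
#'
#' The TSS is the 5'-most base of each record: for a plus-strand gene the
#' first base of its range, for a minus-strand gene the last. Identical
#' (chromosome, position) TSSs within a gene — alternative transcripts
#' sharing a start — collapse to one.
#'
#' @param annotation A stranded `GRanges` with a `gene_id` metadata column,
#'   as from [read_gene_annotation()].
#' @return A width-1 `GRanges` of unique TSS positions with a `gene_id`
#'   column; one row per distinct (gene, position).
#' @export
extract_tss <- function(annotation) {
  stopifnot(is(annotation, "GRanges"))
  if (is.null(mcols(annotation)$gene_id)) {
    stop("annotation must carry a 'gene_id' metadata column")
  }
  st <- as.character(strand(annotation))
  if (any(st == "*")) stop("annotation records must be stranded (+ or -)")
  pos <- ifelse(st == "-", end(annotation), start(annotation))
  tss <- GRanges(seqnames(annotation), IRanges(pos, width = 1L), strand = st,
                 gene_id = mcols(annotation)$gene_id)
  seqinfo(tss) <- seqinfo(annotation)
  key <- paste(mcols(tss)$gene_id, as.character(seqnames(tss)), pos)
  tss[!duplicated(key)]
}

#' Build symmetric flanking windows around TSSs
#'
#' For each TSS a window extends `flank` bases on each side of the TSS
#' base (width `2*flank + 1` on an unbounded chromosome), clipped to the
#' chromosome bounds. Overlapping windows of the *same* gene — alternative
#' TSSs closer together than `2*flank` — are merged so each gene
#' contributes one set of disjoint windows; windows of different genes are
#' never merged, because the downstream analysis counts genes.
#'
#' @param tss A width-1 `GRanges` with `gene_id`, from [extract_tss()].
#' @param flank Flank size in bp, `> 0`. The analyses in this package use
#'   10000 and 1000.
#' @param layout A `Seqinfo` layout used to clip windows; TSS positions
#'   outside the layout are an error.
#' @return A named `GRangesList`, one element per gene, each a sorted
#'   disjoint set of windows.
#' @export
build_windows <- function(tss, flank, layout = seqinfo(tss)) {
  stopifnot(is(tss, "GRanges"), all(width(tss) == 1L))
  if (length(flank) != 1 || !is.finite(flank) || flank <= 0) {
    stop("'flank' must be a single positive number of base pairs")
  }
  if (is.null(mcols(tss)$gene_id)) {
    stop("'tss' must carry a 'gene_id' metadata column")
  }
  tss <- .attach_layout(granges_with_id(tss), layout, "TSS")
  lens <- seqlengths(layout)[as.character(seqnames(tss))]
  win <- GRanges(seqnames(tss),
                 IRanges(pmax(1, start(tss) - flank),
                         pmin(lens, start(tss) + flank)),
                 gene_id = mcols(tss)$gene_id)
  seqinfo(win) <- layout
  grl <- GenomicRanges::reduce(
    GenomicRanges::split(granges(win), mcols(win)$gene_id),
    min.gapwidth = 1L)
  grl
}

# strip mcols to gene_id only, keep strand out of bounds checks
granges_with_id <- function(gr) {
  out <- granges(gr)
  strand(out) <- "*"
  mcols(out)$gene_id <- mcols(gr)$gene_id
  out
}

#' Flag genes whose TSS windows overlap any peak
#'
#' A gene is flagged `TRUE` when at least one of its windows intersects at
#' least one peak by >= 1 bp. Abutting (book-ended) windows and peaks do
#' not count as overlapping.
#'
#' @param windows A `GRangesList` from [build_windows()].
#' @param peaks A `GRanges` peak set on the same layout.
#' @return A named logical vector, one element per gene in `windows`.
#' @export
gene_overlaps_peaks <- function(windows, peaks) {
  stopifnot(is(windows, "GRangesList"), is(peaks, "GRanges"))
  .check_same_layout(unlist(windows, use.names = FALSE), peaks)
  flat <- unlist(windows, use.names = TRUE)
  hit <- overlapsAny(flat, peaks, minoverlap = 1L, ignore.strand = TRUE)
  out <- tapply(hit, factor(names(flat), levels = names(windows)), any)
  res <- as.logical(out)
  names(res) <- names(windows)
  res
}
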