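#' Build a sliding-window bin grid over a genome
#'
#' Partitions each chromosome into fixed-width bins on a sliding grid:
#' bin starts at 0, `step`, 2·`step`, ... (0-based) while the start lies
#' inside the chromosome, each bin `bin_size` bp wide and truncated at the
#' chromosome end. With the defaults (1000 bp bins, 500 bp step) every
#' interior base is covered by two bins. The grid is anchored at coordinate
#' 0 of each chromosome, and truncated terminal bins are emitted like any
#' other bin, so no base of the genome is excluded.
#'
#' @param layout A `Seqinfo` genome layout.
#' @param bin_size Bin width in bp (default 1000).
#' @param step Distance between consecutive bin starts in bp (default 500);
#'   must satisfy `0 < step <= bin_size`.
#' @return A `GRanges` of bins ordered by chromosome (layout order) then
#'   start.
#' @examples
#' layout <- genome_layout("chr1", 2000)
#' make_bins(layout)  # [0,1000), [500,1500), [1000,2000), [1500,2000) in BED coords
#' @export
make_bins <- function(layout, bin_size = 1000, step = 500) {
  stopifnot(is(layout, "Seqinfo"))
  if (!(step > 0 && step <= bin_size)) {
    stop("require 0 < step <= bin_size")
  }
  lens <- seqlengths(layout)
  starts_list <- lapply(lens, function(L) seq.int(0L, L - 1L, by = step))
  starts0 <- unlist(starts_list, use.names = FALSE)
  chrom <- rep(seqnames(layout), lengths(starts_list))
  L <- rep(lens, lengths(starts_list))
  bins <- GRanges(factor(chrom, levels = seqnames(layout)),
                  IRanges(starts0 + 1, pmin(starts0 + bin_size, L)))
  seqinfo(bins) <- layout
  bins
}

#' Count tags per bin
#'
#' Tallies aligned tags into bins under one of two counting modes:
#' \describe{
#'   \item{`five_prime_start`}{a tag is counted in every bin containing its
#'     5' position (plus strand: the tag start; minus strand: the last base;
#'     unstranded: the start). Each tag contributes to exactly the bins
#'     covering one base, which gives exact count-conservation properties.}
#'   \item{`any_overlap`}{a tag is counted in every bin it overlaps by at
#'     least 1 bp, as a `bedtools intersect` workflow would count.}
#' }
#' Counts are multiset counts: duplicate tags count once each.
#'
#' @param bins Bins from [make_bins()].
#' @param tags A `GRanges` tag set on the same layout.
#' @param mode Counting mode, `"five_prime_start"` (default) or
#'   `"any_overlap"`.
#' @return `bins` with an integer metadata column `tag_count`.
#' @export
count_tags <- function(bins, tags, mode = c("five_prime_start", "any_overlap")) {
  mode <- match.arg(mode)
  .check_same_layout(bins, tags)
  if (mode == "five_prime_start") {
    pos <- five_prime_pos(tags)
    n <- countOverlaps(bins, pos, ignore.strand = TRUE)
  } else {
    n <- countOverlaps(bins, tags, ignore.strand = TRUE, minoverlap = 1L)
  }
  mcols(bins)$tag_count <- n
  bins
}

#' 5' positions of tags
#'
#' Width-1 ranges at each tag's 5' end: the start for plus-strand and
#' unstranded tags, the last covered base for minus-strand tags.
#'
#' @param tags A `GRanges`.
#' @return A width-1 `GRanges`, same length and order as `tags`.
#' @export
five_prime_pos <- function(tags) {
  pos <- ifelse(as.character(strand(tags)) == "-", end(tags), start(tags))
  out <- GRanges(seqnames(tags), IRanges(pos, width = 1L))
  seqinfo(out) <- seqinfo(tags)
  out
}

#' Call peaks from counted bins by thresholding and merging
#'
#' Selects bins whose tag count exceeds `threshold` (strictly, by default)
#' and merges the selected bin intervals — overlapping and book-ended —
#' into maximal peaks via [merge_intervals()].
#'
#' @param counted Bins with a `tag_count` column, from [count_tags()].
#' @param threshold Tag-count threshold (default 500). With `strict = TRUE`
#'   a bin passes only when `tag_count > threshold`.
#' @param strict Use strict `>` comparison (default `TRUE`); `FALSE` uses
#'   `>=`.
#' @return A sorted disjoint `GRanges` peak set.
#' @examples
#' layout <- genome_layout("chr1", 2000)
#' bins <- make_bins(layout)
#' S4Vectors::mcols(bins)$tag_count <- c(600L, 700L, 10L, 0L)
#' call_peaks(bins)  # single peak chr1:1-1500
#' @export
call_peaks <- function(counted, threshold = 500, strict = TRUE) {
  if (is.null(mcols(counted)$tag_count)) {
    stop("'counted' must carry a 'tag_count' column; run count_tags() first")
  }
  if (length(threshold) != 1 || !is.finite(threshold) || threshold < 0) {
    stop("'threshold' must be a single non-negative number")
  }
  n <- mcols(counted)$tag_count
  pass <- if (strict) n > threshold else n >= threshold
  merge_intervals(counted[pass])
}

#' Run the full peak-calling pipeline from files
#'
#' Reads one or more BED tag files (multiple files are pooled before
#' counting, e.g. merged replicates) and a chromosome-sizes file, builds the
#' bin grid, counts tags, thresholds and merges, and optionally writes the
#' peak BED and a JSON summary.
#'
#' @param tag_paths Character vector of BED tag file paths; pooled.
#' @param layout_path Path to a chrom.sizes file.
#' @param bin_size,step Grid parameters, see [make_bins()].
#' @param threshold,strict Peak threshold, see [call_peaks()].
#' @param mode Counting mode, see [count_tags()].
#' @param dedup Remove duplicate tag intervals before counting (default
#'   `FALSE`: duplicates kept, multiset semantics).
#' @param out Optional path for the peaks BED file.
#' @param summary_path Optional path for a JSON summary.
#' @return A list with elements `peaks` (`GRanges`) and `summary` (list:
#'   `n_tags`, `bins_total`, `bins_passing`, `n_peaks`, `bases_covered`).
#' @export
run_peak_calling <- function(tag_paths, layout_path, bin_size = 1000,
                             step = 500, threshold = 500, strict = TRUE,
                             mode = "five_prime_start", dedup = FALSE,
                             out = NULL, summary_path = NULL) {
  layout <- read_chrom_sizes(layout_path)
  tags <- do.call(c, lapply(tag_paths, read_bed, layout = layout))
  if (dedup) tags <- unique(tags)
  bins <- make_bins(layout, bin_size = bin_size, step = step)
  counted <- count_tags(bins, tags, mode = mode)
  peaks <- call_peaks(counted, threshold = threshold, strict = strict)
  n <- mcols(counted)$tag_count
  summary <- list(
    n_tags = length(tags),
    bins_total = length(bins),
    bins_passing = sum(if (strict) n > threshold else n >= threshold),
    n_peaks = length(peaks),
    bases_covered = covered_bases(peaks)
  )
  if (!is.null(out)) write_bed(peaks, out)
  if (!is.null(summary_path)) {
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE)
  }
  list(peaks = peaks, summary = summary)
}

.check_same_layout <- function(a, b) {
  sa <- seqlengths(a); sb <- seqlengths(b)
  sa <- sa[!is.na(sa)]; sb <- sb[!is.na(sb)]
  if (length(sa) == 0 || length(sb) == 0) {
    return(invisible(TRUE))  # one side carries no layout: nothing to check
  }
  common <- intersect(names(sa), names(sb))
  if (length(common) == 0 ||
      !identical(unname(sa[common]), unname(sb[common]))) {
    stop("genome layouts of the two objects do not match")
  }
  invisible(TRUE)
}
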