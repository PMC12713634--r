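#' Read intervals from a BED file
#'
#' Parses BED3 or BED6 (tab-separated, no header) into a
#' [GenomicRanges::GRanges]. BED coordinates are 0-based half-open; they are
#' converted to the 1-based closed convention `GRanges` uses, so a BED line
#' `chr1  0  36` becomes the range `chr1:1-36`. Strand is taken from column
#' 6 when present (`+`, `-`, or `.` for unstranded), the name column is kept
#' as metadata column `name`, and duplicate lines are preserved (tag sets
#' are multisets).
#'
#' @param path Path to a BED3/BED6 file.
#' @param layout Optional `Seqinfo` layout. When given, records on unknown
#'   chromosomes or outside chromosome bounds are an error and the returned
#'   object carries the layout as its `seqinfo`.
#' @return A `GRanges`, in file order, with a `name` metadata column when
#'   the file has one.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t36", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path, layout = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(if (is.null(layout)) GRanges() else GRanges(seqinfo = layout))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    stop("malformed BED line ", which(ncols < 3)[1], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s_chr <- vapply(fields, `[[`, "", 2L)
  e_chr <- vapply(fields, `[[`, "", 3L)
  start0 <- suppressWarnings(as.numeric(s_chr))
  end0 <- suppressWarnings(as.numeric(e_chr))
  bad_num <- !is.finite(start0) | !is.finite(end0) |
    start0 != floor(start0) | end0 != floor(end0)
  if (any(bad_num)) {
    stop("malformed BED line ", which(bad_num)[1], ": non-integer coordinates")
  }
  bad_iv <- start0 >= end0 | start0 < 0
  if (any(bad_iv)) {
    stop("malformed BED line ", which(bad_iv)[1],
         ": start must satisfy 0 <= start < end")
  }
  strand <- rep("*", length(lines))
  if (all(ncols >= 6)) {
    st <- vapply(fields, `[[`, "", 6L)
    bad_st <- !st %in% c("+", "-", ".")
    if (any(bad_st)) {
      stop("malformed BED line ", which(bad_st)[1], ": invalid strand '",
           st[which(bad_st)[1]], "'")
    }
    strand <- ifelse(st == ".", "*", st)
  }
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = strand)
  if (all(ncols >= 4)) {
    mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  }
  if (!is.null(layout)) {
    gr <- .attach_layout(gr, layout, "BED record")
  } else {
    seqlevels(gr) <- unique(chrom)
  }
  gr
}

#' Write intervals to a BED file
#'
#' Writes a `GRanges` as BED, converting back to BED's 0-based half-open
#' coordinates. Output is BED3 when all ranges are unstranded and there is
#' no `name` column, BED6 otherwise (name `.` or the `name` metadata column,
#' score `0`). `read_bed(write_bed(x))` reproduces the interval multiset of
#' `x` exactly.
#'
#' @param gr A `GRanges` (a tag set, peak set, or annotation).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  start0 <- format(start(gr) - 1, scientific = FALSE, trim = TRUE)
  end0 <- format(end(gr), scientific = FALSE, trim = TRUE)
  st <- as.character(strand(gr))
  has_name <- !is.null(mcols(gr)$name)
  if (all(st == "*") && !has_name) {
    txt <- paste(as.character(seqnames(gr)), start0, end0, sep = "\t")
  } else {
    nm <- if (has_name) as.character(mcols(gr)$name) else rep(".", length(gr))
    txt <- paste(as.character(seqnames(gr)), start0, end0, nm, "0",
                 ifelse(st == "*", ".", st), sep = "\t")
  }
  writeLines(txt, path)
  invisible(path)
}

#' Read a gene annotation (BED6 or GTF)
#'
#' Reads gene records with mandatory strand. BED6 input takes the gene
#' identifier from the name column. GTF input (1-based inclusive; converted
#' on read by the parser) uses `gene` features by default, falling back to
#' `transcript` features when no `gene` features are present; transcript
#' TSSs are later collapsed per gene by [extract_tss()].
#'
#' @param path Path to a BED6 or GTF file.
#' @param format `"bed"` or `"gtf"`; guessed from the file extension by
#'   default.
#' @param layout Optional `Seqinfo` layout for bounds checking.
#' @param gene_id_attr GTF attribute holding the gene identifier
#'   (default `"gene_id"`).
#' @return A `GRanges` with a `gene_id` metadata column; every range
#'   stranded `+` or `-`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gtf"),
                                 layout = NULL, gene_id_attr = "gene_id") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)[0-9]?$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  if (format == "bed") {
    gr <- read_bed(path, layout = layout)
    if (is.null(mcols(gr)$name)) {
      stop("BED annotation must be BED6 with gene ids in the name column")
    }
    mcols(gr) <- S4Vectors::DataFrame(gene_id = mcols(gr)$name)
  } else {
    gtf <- rtracklayer::import(path, format = "gtf")
    keep <- gtf$type == "gene"
    if (!any(keep)) keep <- gtf$type == "transcript"
    if (!any(keep)) stop("GTF contains no 'gene' or 'transcript' features")
    gr <- gtf[keep]
    ids <- mcols(gr)[[gene_id_attr]]
    if (is.null(ids)) {
      stop("GTF attribute '", gene_id_attr, "' not found")
    }
    mcols(gr) <- S4Vectors::DataFrame(gene_id = as.character(ids))
    if (!is.null(layout)) gr <- .attach_layout(gr, layout, "gene")
  }
  if (any(as.character(strand(gr)) == "*")) {
    stop("gene annotation records must be stranded (+ or -)")
  }
  gr
}
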