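#' Define a genome layout
#'
#' A genome layout is the coordinate frame for all interval operations: an
#' ordered set of chromosomes with known lengths. It is represented as a
#' [GenomeInfoDb::Seqinfo] object; chromosome order is the order given here
#' (not lexicographic), so all sorted output is deterministic and
#' locale-independent.
#'
#' @param seqnames Character vector of unique chromosome names.
#' @param seqlengths Integer vector of chromosome lengths in base pairs,
#'   all strictly positive, same length as `seqnames`.
#'
#' @return A `Seqinfo` object.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(10000L, 5000L))
#' @export
genome_layout <- function(seqnames, seqlengths) {
  seqnames <- as.character(seqnames)
  if (anyDuplicated(seqnames)) {
    stop("chromosome names must be unique")
  }
  if (length(seqnames) != length(seqlengths)) {
    stop("'seqnames' and 'seqlengths' must have the same length")
  }
  seqlengths <- as.numeric(seqlengths)
  if (any(!is.finite(seqlengths)) || any(seqlengths <= 0) ||
      any(seqlengths != floor(seqlengths))) {
    stop("chromosome lengths must be strictly positive integers")
  }
  Seqinfo(seqnames = seqnames, seqlengths = as.integer(seqlengths))
}

#' Read a chromosome-sizes file
#'
#' Reads the standard two-column tab-separated `chrom.sizes` format
#' (chromosome name, length in bp; no header).
#'
#' @param path Path to the chrom.sizes file.
#' @return A [GenomeInfoDb::Seqinfo] layout, chromosomes in file order.
#' @seealso [genome_layout()]
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = c("character", "numeric"),
                   col.names = c("chrom", "length"))
  if (ncol(df) < 2 || nrow(df) == 0) {
    stop("chrom.sizes file must have two columns: name, length")
  }
  genome_layout(df$chrom, df$length)
}

#' Write a genome layout as a chromosome-sizes file
#'
#' @param layout A `Seqinfo` layout.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(layout, path) {
  df <- data.frame(chrom = seqnames(layout), length = seqlengths(layout))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Check that `gr` fits inside `layout`; returns gr with seqinfo attached.
.attach_layout <- function(gr, layout, what = "interval") {
  bad <- setdiff(unique(as.character(seqnames(gr))), seqnames(layout))
  if (length(bad)) {
    stop("unknown chromosome(s) not in layout: ", paste(bad, collapse = ", "))
  }
  seqlevels(gr) <- seqnames(layout)
  lens <- seqlengths(layout)[as.character(seqnames(gr))]
  if (any(start(gr) < 1) || any(end(gr) > lens)) {
    stop(what, "(s) out of chromosome bounds")
  }
  seqinfo(gr) <- layout
  gr
}
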