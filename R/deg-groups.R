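#' Read a DESeq2-style differential-expression results table
#'
#' Reads a tab-separated results table with a header row containing, at
#' minimum, a gene identifier, `baseMean`, `log2FoldChange` and `padj`
#' column (a `pvalue` column is kept when present). `NA` cells parse as
#' missing, the DESeq2 convention for genes removed by independent
#' filtering.
#'
#' @param path Path to the TSV file.
#' @param columns Named character vector mapping the canonical names
#'   `gene_id`, `baseMean`, `log2FoldChange`, `pvalue`, `padj` to the
#'   column names used in the file. Only entries that differ from the
#'   defaults need to be given.
#' @return A `data.frame` with columns `gene_id`, `baseMean`,
#'   `log2FoldChange`, `pvalue` (all-`NA` when absent from the file), and
#'   `padj`; one row per gene.
#' @export
read_deg_table <- function(path, columns = character()) {
  map <- c(gene_id = "gene_id", baseMean = "baseMean",
           log2FoldChange = "log2FoldChange", pvalue = "pvalue",
           padj = "padj")
  map[names(columns)] <- columns
  df <- read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                   check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("gene_id", "baseMean", "log2FoldChange", "padj")
  missing_cols <- required[!map[required] %in% names(df)]
  if (length(missing_cols)) {
    stop("DEG table is missing required column(s): ",
         paste(map[missing_cols], collapse = ", "))
  }
  out <- data.frame(
    gene_id = as.character(df[[map["gene_id"]]]),
    baseMean = .num_col(df, map["baseMean"]),
    log2FoldChange = .num_col(df, map["log2FoldChange"]),
    pvalue = if (map["pvalue"] %in% names(df)) .num_col(df, map["pvalue"])
             else NA_real_,
    padj = .num_col(df, map["padj"]),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$gene_id) | is.na(out$gene_id))) {
    stop("empty gene identifier at row ",
         which(!nzchar(out$gene_id) | is.na(out$gene_id))[1])
  }
  if (anyDuplicated(out$gene_id)) {
    stop("duplicated gene_id: ",
         out$gene_id[anyDuplicated(out$gene_id)])
  }
  out
}

.num_col <- function(df, name) {
  raw <- df[[name]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & !is.na(raw) & raw != "NA")
  if (length(bad)) {
    stop("unparseable numeric in column '", name, "' at row ", bad[1])
  }
  val
}

#' Classify genes into up, down, unchanged and excluded groups
#'
#' Partitions a differential-expression table into the three analysis
#' groups plus an excluded remainder:
#' \describe{
#'   \item{up}{`padj` present, `padj < padj_cutoff`, and
#'     `log2FoldChange > lfc_cutoff`.}
#'   \item{down}{`padj` present, `padj < padj_cutoff`, and
#'     `log2FoldChange < -lfc_cutoff`.}
#'   \item{unchanged}{not significant (`padj` missing or `>= padj_cutoff`)
#'     and `baseMean > base_cutoff` — expressed genes with no detected
#'     change, the control group.}
#'   \item{excluded}{everything else; chiefly non-significant genes whose
#'     baseline expression does not clear `base_cutoff`.}
#' }
#' The comparison with `base_cutoff` is strict (`> base_cutoff`). Genes
#' with missing `padj` (DESeq2 independent filtering) are treated as not
#' significant and routed to unchanged or excluded by `baseMean`. The four
#' groups are pairwise disjoint and jointly exhaust the table.
#'
#' @param deg A data frame as from [read_deg_table()].
#' @param padj_cutoff Adjusted-p significance cutoff (default 0.05).
#' @param lfc_cutoff Non-negative log2-fold-change magnitude cutoff
#'   (default 0: any significant change counts).
#' @param base_cutoff Baseline-expression (baseMean) cutoff for the
#'   unchanged group (default 1; strict `>`).
#' @return An object of class `gene_groups`: a list with character-vector
#'   elements `up`, `down`, `unchanged`, `excluded`, plus the cutoffs as
#'   attributes.
#' @export
classify_genes <- function(deg, padj_cutoff = 0.05, lfc_cutoff = 0,
                           base_cutoff = 1) {
  stopifnot(is.data.frame(deg), lfc_cutoff >= 0)
  sig <- !is.na(deg$padj) & deg$padj < padj_cutoff
  up <- sig & deg$log2FoldChange > lfc_cutoff
  down <- sig & deg$log2FoldChange < -lfc_cutoff
  unchanged <- !sig & !is.na(deg$baseMean) & deg$baseMean > base_cutoff
  excluded <- !(up | down | unchanged)
  structure(
    list(up = deg$gene_id[up], down = deg$gene_id[down],
         unchanged = deg$gene_id[unchanged],
         excluded = deg$gene_id[excluded]),
    class = "gene_groups",
    padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff,
    base_cutoff = base_cutoff
  )
}

#' @export
print.gene_groups <- function(x, ...) {
  cat("Gene groups (padj <", attr(x, "padj_cutoff"),
      ", |lfc| >", attr(x, "lfc_cutoff"),
      ", baseMean >", attr(x, "base_cutoff"), "):\n")
  cat(sprintf("  up: %d  down: %d  unchanged: %d  excluded: %d\n",
              length(x$up), length(x$down), length(x$unchanged),
              length(x$excluded)))
  invisible(x)
}

#' Write gene-group lists to text files
#'
#' One file per group (`up.txt`, `down.txt`, `unchanged.txt`,
#' `excluded.txt`), one gene id per line.
#'
#' @param groups A `gene_groups` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths.
#' @export
write_gene_lists <- function(groups, dir) {
  stopifnot(inherits(groups, "gene_groups"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(names(groups), ".txt"))
  for (i in seq_along(groups)) writeLines(groups[[i]], paths[i])
  invisible(paths)
}
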