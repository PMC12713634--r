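#' Per-group peak-overlap frequencies
#'
#' For each gene group (up, down, unchanged) counts how many genes have a
#' TSS window overlapping at least one peak, and the corresponding
#' proportion. Excluded genes are ignored. Grouped genes missing from
#' `flags` (no annotation entry) are dropped from the denominator and
#' reported in the `n_dropped` attribute. A group with zero annotated
#' genes gets an `NA` proportion rather than an error.
#'
#' @param groups A `gene_groups` object from [classify_genes()].
#' @param flags Named logical vector of per-gene overlap flags from
#'   [gene_overlaps_peaks()].
#' @return A `data.frame` with columns `group` (`up`, `down`, `unchanged`),
#'   `n_genes`, `n_overlapping`, `proportion`; attribute `n_dropped` gives
#'   per-group counts of grouped genes without a flag.
#' @export
overlap_frequency <- function(groups, flags) {
  stopifnot(inherits(groups, "gene_groups"), is.logical(flags))
  if (is.null(names(flags)) && length(flags) > 0) {
    stop("'flags' must be a named logical vector (names = gene ids)")
  }
  grp_names <- c("up", "down", "unchanged")
  rows <- lapply(grp_names, function(g) {
    ids <- groups[[g]]
    have <- ids[ids %in% names(flags)]
    n <- length(have)
    k <- sum(flags[have])
    data.frame(group = g, n_genes = n, n_overlapping = k,
               proportion = if (n > 0) k / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_dropped") <- vapply(
    grp_names, function(g) sum(!groups[[g]] %in% names(flags)), integer(1))
  out
}

#' Pooled two-proportion Z-test
#'
#' Tests equality of two binomial proportions with the pooled
#' normal-approximation statistic
#' \deqn{z = \frac{\hat p_1 - \hat p_2}
#'   {\sqrt{\hat p (1 - \hat p)(1/n_1 + 1/n_2)}},\qquad
#'   \hat p = \frac{x_1 + x_2}{n_1 + n_2}.}
#' The two-sided p-value is `2 * (1 - pnorm(abs(z)))`. When the pooled
#' proportion is 0 or 1 the variance estimate vanishes; the result is then
#' returned as `z = 0`, `p = 1` with `degenerate = TRUE`. Equal observed
#' proportions give `z = 0`, `p = 1` exactly.
#'
#' @param x1,n1 Successes and trials in the first sample (`n1 >= 1`).
#' @param x2,n2 Successes and trials in the second sample (`n2 >= 1`).
#' @param alternative `"two.sided"` (default), `"greater"` (p1 > p2) or
#'   `"less"`.
#' @return A list of class `z_test` with elements `z`, `p_value`,
#'   `estimate` (the two proportions), `alternative` and `degenerate`.
#' @examples
#' two_proportion_z(30, 100, 10, 100)  # z = 3.5355, p = 4.07e-4
#' @export
two_proportion_z <- function(x1, n1, x2, n2,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  for (v in list(x1, n1, x2, n2)) {
    if (length(v) != 1 || !is.finite(v) || v < 0) {
      stop("counts must be single non-negative finite numbers")
    }
  }
  if (n1 < 1 || n2 < 1) stop("both sample sizes must be >= 1")
  if (x1 > n1 || x2 > n2) stop("successes cannot exceed trials")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  degenerate <- pooled <= 0 || pooled >= 1
  if (degenerate || p1 == p2) {
    z <- 0
  } else {
    z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  }
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  structure(list(z = z, p_value = p, estimate = c(p1 = p1, p2 = p2),
                 alternative = alternative, degenerate = degenerate),
            class = "z_test")
}

#' @export
print.z_test <- function(x, ...) {
  cat(sprintf("Two-proportion Z-test (%s): z = %.4f, p = %.4g%s\n",
              x$alternative, x$z, x$p_value,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' Group enrichment report: frequencies plus pairwise Z-tests
#'
#' Computes [overlap_frequency()] for the up/down/unchanged groups and the
#' three pairwise pooled Z-tests: up vs unchanged, down vs unchanged, and
#' up vs down. Raw p-values are reported by default (three tests, no
#' multiplicity correction); `bonferroni = TRUE` multiplies them by 3 and
#' caps at 1.
#'
#' @inheritParams overlap_frequency
#' @param alternative Sidedness passed to [two_proportion_z()]. The default
#'   is two-sided; `"greater"` tests the directional hypothesis that the
#'   first group of each pair is the more frequently bound.
#' @param bonferroni Apply Bonferroni correction across the three
#'   comparisons (default `FALSE`).
#' @return A list of class `enrichment_result`: `counts` (the frequency
#'   data frame) and `tests` (data frame with columns `comparison`, `z`,
#'   `p_value`, `degenerate`). Comparisons involving a group with no
#'   annotated genes get `NA` statistics.
#' @export
run_enrichment <- function(groups, flags,
                           alternative = "two.sided", bonferroni = FALSE) {
  counts <- overlap_frequency(groups, flags)
  rownames(counts) <- counts$group
  pairs <- list(c("up", "unchanged"), c("down", "unchanged"), c("up", "down"))
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- counts[pr[1], ]
    b <- counts[pr[2], ]
    if (a$n_genes == 0 || b$n_genes == 0) {
      return(data.frame(comparison = paste(pr, collapse = "_vs_"),
                        z = NA_real_, p_value = NA_real_, degenerate = NA,
                        stringsAsFactors = FALSE))
    }
    zt <- two_proportion_z(a$n_overlapping, a$n_genes,
                           b$n_overlapping, b$n_genes,
                           alternative = alternative)
    data.frame(comparison = paste(pr, collapse = "_vs_"),
               z = zt$z, p_value = zt$p_value, degenerate = zt$degenerate,
               stringsAsFactors = FALSE)
  }))
  if (bonferroni) tests$p_value <- pmin(1, tests$p_value * nrow(tests))
  structure(list(counts = counts, tests = tests,
                 alternative = alternative, bonferroni = bonferroni),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("TSS-window peak-overlap enrichment\n")
  print(x$counts, row.names = FALSE)
  cat("\nPairwise two-proportion Z-tests (", x$alternative,
      if (x$bonferroni) ", Bonferroni-corrected" else "", "):\n", sep = "")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Write an enrichment report to TSV and/or JSON
#'
#' @param result An `enrichment_result`.
#' @param tsv_path,json_path Optional output paths; the TSV contains the
#'   counts table followed by a blank line and the tests table.
#' @return Invisibly, `result`.
#' @export
write_enrichment <- function(result, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "enrichment_result"))
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    on.exit(close(con))
    write.table(result$counts, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines("", con)
    write.table(result$tests, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(counts = result$counts, tests = result$tests),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(result)
}

#' Two-sample t-test (Welch or pooled-variance Student)
#'
#' The Welch statistic
#' \deqn{t = \frac{\bar x_1 - \bar x_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}}
#' with Satterthwaite degrees of freedom, or the classical pooled-variance
#' Student variant with `pooled = TRUE`. Two-sided p-value from the t
#' distribution.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance (equal-variance) Student test
#'   (default `FALSE`, i.e. Welch).
#' @return A list with elements `t`, `df`, `p_value`, `estimate`
#'   (the two means).
#' @export
welch_t_test <- function(x, y, pooled = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2 || anyNA(x) || anyNA(y)) {
    stop("both samples must have >= 2 non-missing values")
  }
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  d <- mean(x) - mean(y)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- v1 / n1; b <- v2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- if (se == 0) 0 else d / se
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df),
       estimate = c(mean1 = mean(x), mean2 = mean(y)))
}

#' Read a long-format qPCR Ct table
#'
#' Tab-separated with a header containing at least `gene`, `sample`, `ct`
#' columns; an optional `condition` column is kept.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `gene`, `sample`, `ct`, and
#'   `condition` when present.
#' @export
read_qpcr_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "sample", "ct")
  if (!all(need %in% names(df))) {
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  }
  df$ct <- .num_col(df, "ct")
  df
}

#' Reference-normalized qPCR expression as per-gene Z-scores
#'
#' Per sample, relative expression of each gene against the reference gene
#' is `r = 2^-(Ct_gene - Ct_reference)` (the delta-Ct method); each gene's
#' relative-expression values are then standardized across samples to mean
#' 0 and standard deviation 1. Genes whose relative expression is constant
#' across samples have zero variance and cannot be standardized: their rows
#' are returned as `NA` and flagged.
#'
#' @param table A long-format data frame as from [read_qpcr_table()]
#'   (columns `gene`, `sample`, `ct`).
#' @param reference Reference gene id; must be measured in every sample.
#' @return A numeric matrix (genes x samples) of Z-scores, the reference
#'   gene excluded, with a logical attribute `zero_variance` flagging
#'   constant rows (returned as `NA`).
#' @export
qpcr_zscore <- function(table, reference) {
  stopifnot(is.data.frame(table),
            all(c("gene", "sample", "ct") %in% names(table)))
  samples <- unique(table$sample)
  ref <- table[table$gene == reference, ]
  if (!all(samples %in% ref$sample)) {
    stop("reference gene '", reference, "' missing in sample(s): ",
         paste(setdiff(samples, ref$sample), collapse = ", "))
  }
  ref_ct <- ref$ct[match(samples, ref$sample)]
  names(ref_ct) <- samples
  genes <- setdiff(unique(table$gene), reference)
  rel <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  for (i in seq_len(nrow(table))) {
    g <- table$gene[i]
    if (g == reference) next
    s <- table$sample[i]
    rel[g, s] <- 2^(-(table$ct[i] - ref_ct[s]))
  }
  if (anyNA(rel)) {
    stop("every non-reference gene must be measured in every sample")
  }
  zero_var <- apply(rel, 1, function(r) stats::sd(r) == 0)
  z <- t(apply(rel, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(NA_real_, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(rel)
  attr(z, "zero_variance") <- zero_var
  z
}
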