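# Brute-force oracles, written independently of the package's code paths:
# everything here works on plain data.frames in BED-style 0-based half-open
# coordinates and per-base logical occupancy vectors, with explicit loops.
# Conversion to/from GRanges happens only at the comparison boundary.

# data.frame(chrom, start0, end0[, strand]) -> GRanges
df_to_gr <- function(df, layout = NULL) {
  gr <- GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(df$start0 + 1, df$end0),
    strand = if ("strand" %in% names(df)) df$strand else "*")
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
  }
  gr
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1,
             end0 = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# per-chromosome boolean occupancy of a set of intervals
oracle_occupancy <- function(df, lens) {
  occ <- lapply(lens, function(L) logical(L))
  for (i in seq_len(nrow(df))) {
    s <- df$start0[i]; e <- df$end0[i]
    if (e > s) occ[[df$chrom[i]]][(s + 1):e] <- TRUE
  }
  occ
}

# occupancy vectors -> maximal intervals (0-based half-open), chrom order
# = order of `lens`
occupancy_to_intervals <- function(occ) {
  out <- list()
  for (chrom in names(occ)) {
    v <- occ[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start0 = starts[keep], end0 = ends[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start0 = numeric(),
                      end0 = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# enumerate the sliding-window bin grid by its definition
oracle_bins <- function(lens, bin_size, step) {
  rows <- list()
  for (chrom in names(lens)) {
    L <- lens[[chrom]]
    s <- 0
    while (s < L) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start0 = s, end0 = min(s + bin_size, L),
        stringsAsFactors = FALSE)
      s <- s + step
    }
  }
  do.call(rbind, rows)
}

# 5' position of a tag in 0-based coordinates
oracle_five_prime <- function(start0, end0, strand) {
  if (strand == "-") end0 - 1 else start0
}

# nested-loop tag counting over bins x tags
oracle_count_tags <- function(bins, tags, mode = "five_prime_start") {
  counts <- integer(nrow(bins))
  for (j in seq_len(nrow(tags))) {
    for (i in seq_len(nrow(bins))) {
      if (bins$chrom[i] != tags$chrom[j]) next
      hit <- if (mode == "five_prime_start") {
        p <- oracle_five_prime(tags$start0[j], tags$end0[j], tags$strand[j])
        p >= bins$start0[i] && p < bins$end0[i]
      } else {
        max(bins$start0[i], tags$start0[j]) < min(bins$end0[i], tags$end0[j])
      }
      if (hit) counts[i] <- counts[i] + 1L
    }
  }
  counts
}

# complete brute-force peak caller: enumerate bins, count, threshold,
# per-base union of passing bins
oracle_call_peaks <- function(tags, lens, bin_size, step, threshold,
                              mode = "five_prime_start", strict = TRUE) {
  bins <- oracle_bins(lens, bin_size, step)
  counts <- oracle_count_tags(bins, tags, mode)
  pass <- if (strict) counts > threshold else counts >= threshold
  if (!any(pass)) {
    return(data.frame(chrom = character(), start0 = numeric(),
                      end0 = numeric(), stringsAsFactors = FALSE))
  }
  occupancy_to_intervals(oracle_occupancy(bins[pass, , drop = FALSE], lens))
}

# per-gene window/peak overlap by boolean occupancy arrays
oracle_gene_overlaps <- function(windows, peaks, lens) {
  peak_occ <- oracle_occupancy(peaks, lens)
  genes <- unique(windows$gene_id)
  flags <- logical(length(genes))
  names(flags) <- genes
  for (g in genes) {
    w <- windows[windows$gene_id == g, , drop = FALSE]
    for (i in seq_len(nrow(w))) {
      s <- w$start0[i]; e <- w$end0[i]
      if (e > s && any(peak_occ[[w$chrom[i]]][(s + 1):e])) {
        flags[g] <- TRUE
        break
      }
    }
  }
  flags
}

# random small instance for oracle-equivalence checks (<= 10 kb genome)
random_instance <- function(seed) {
  set.seed(seed)
  n_chrom <- sample(1:2, 1)
  lens <- sample(2000:6000, n_chrom)
  names(lens) <- paste0("chr", seq_len(n_chrom))
  layout <- tssenrich::genome_layout(names(lens), lens)
  n_tags <- sample(50:250, 1)
  chrom <- sample(names(lens), n_tags, replace = TRUE)
  start0 <- vapply(chrom, function(cn) sample(0:(lens[[cn]] - 2), 1),
                   numeric(1))
  width <- sample(10:50, n_tags, replace = TRUE)
  end0 <- pmin(start0 + width, lens[chrom])
  tags <- data.frame(chrom = chrom, start0 = start0, end0 = end0,
                     strand = sample(c("+", "-", "*"), n_tags, replace = TRUE),
                     stringsAsFactors = FALSE)
  bin_size <- sample(c(200, 500, 1000), 1)
  steps <- c(100, 200, 250, 500)
  list(layout = layout, lens = lens, tags = tags,
       bin_size = bin_size,
       step = sample(steps[steps <= bin_size], 1),
       threshold = sample(0:4, 1))
}
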