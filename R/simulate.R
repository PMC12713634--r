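#' Configuration for the synthetic ChIP-seq / RNA-seq data generator
#'
#' Bundles and validates all generator parameters. The generator emulates
#' the statistical structure the integration analysis assumes: a toy
#' multi-chromosome genome, stranded gene annotations with three latent
#' expression groups plus an excluded low-expression remainder, a
#' DESeq2-style results table consistent with those groups, and a ChIP tag
#' set with one binding site planted near a gene's TSS with a
#' group-specific probability, over a uniform background.
#'
#' Genes are placed on a regular grid of candidate TSS slots with spacing
#' `2 * flank_used + guard`, so TSS windows of different genes never
#' overlap and (with the default guard) a peak planted at one gene cannot
#' reach a neighbour's window — planted-truth evaluation stays
#' unambiguous. The configuration is rejected when the genome cannot hold
#' the requested genes at that spacing.
#'
#' The background constraint is checked at validation time: the expected
#' background tag count per bin is `background_tag_rate * bin_size / 1000`
#' (each 5' position lands in `bin_size / step` bins, but each bin spans
#' `bin_size` bp, so the expectation per bin is the per-bp rate times the
#' bin width); it must stay below `threshold / 2` so background alone can
#' never approach a peak call.
#'
#' @param seed Master seed; every random draw in the generator flows from
#'   it (each stage re-seeds with a fixed offset of the master seed so the
#'   stages are also individually reproducible).
#' @param n_chromosomes,chrom_length Genome shape (default 3 x 3 Mb).
#' @param n_up,n_down,n_unchanged,n_excluded Genes per latent group
#'   (defaults 60/60/60/30).
#' @param flank_used TSS flank (bp) the downstream analysis will use;
#'   drives gene spacing (default 10000).
#' @param p_bind Named probabilities (`up`, `down`, `unchanged`) that a
#'   gene of that group receives a planted binding site in its TSS window
#'   (defaults 0.6/0.1/0.1; excluded genes are never bound).
#' @param tags_per_site Tags emitted per planted site (default 1000, twice
#'   the caller threshold, so every bin fully covering a site's tag cloud
#'   passes comfortably).
#' @param background_tag_rate Background tags per kb of genome (default 1).
#' @param tag_length Tag (read) length in bp (default 36).
#' @param site_jitter_sd SD (bp) of the planted site centre's offset from
#'   the TSS, clipped into the flank window (default 2000).
#' @param tag_jitter_sd SD (bp) of tag 5' positions around the site centre
#'   (default 50).
#' @param bin_size,step,threshold Peak-caller parameters the simulation is
#'   calibrated against (defaults 1000/500/500).
#' @param gene_length_range Range (bp) of simulated gene lengths
#'   (default 1000-10000).
#' @param guard Extra spacing (bp) between adjacent TSS slots beyond
#'   `2 * flank_used` (default 5000, comfortably more than the maximal
#'   planted-peak half-width).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 3, chrom_length = 3e6,
                              n_up = 60, n_down = 60, n_unchanged = 60,
                              n_excluded = 30,
                              flank_used = 10000,
                              p_bind = c(up = 0.6, down = 0.1, unchanged = 0.1),
                              tags_per_site = 1000,
                              background_tag_rate = 1,
                              tag_length = 36,
                              site_jitter_sd = 2000,
                              tag_jitter_sd = 50,
                              bin_size = 1000, step = 500, threshold = 500,
                              gene_length_range = c(1000, 10000),
                              guard = 5000) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chrom_length = chrom_length, n_up = n_up, n_down = n_down,
              n_unchanged = n_unchanged, n_excluded = n_excluded,
              flank_used = flank_used, p_bind = p_bind,
              tags_per_site = tags_per_site,
              background_tag_rate = background_tag_rate,
              tag_length = tag_length, site_jitter_sd = site_jitter_sd,
              tag_jitter_sd = tag_jitter_sd, bin_size = bin_size,
              step = step, threshold = threshold,
              gene_length_range = gene_length_range, guard = guard)
  if (!all(c("up", "down", "unchanged") %in% names(p_bind)) ||
      any(p_bind < 0 | p_bind > 1)) {
    stop("'p_bind' must be named (up, down, unchanged) probabilities in [0,1]")
  }
  pos <- c(n_chromosomes, chrom_length, flank_used, tags_per_site,
           tag_length, bin_size, step, threshold, guard)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all sizes, counts and rates must be positive")
  }
  if (site_jitter_sd < 0 || tag_jitter_sd < 0 || background_tag_rate < 0) {
    stop("jitter SDs and background rate must be non-negative")
  }
  exp_bg_per_bin <- background_tag_rate * bin_size / 1000
  if (exp_bg_per_bin >= threshold / 2) {
    stop("background too dense: expected background tags per bin (",
         exp_bg_per_bin, " = background_tag_rate * bin_size / 1000) must be ",
         "below threshold / 2 (", threshold / 2, ")")
  }
  cfg$spacing <- 2 * flank_used + guard
  cfg$margin <- flank_used + max(gene_length_range)
  n_genes <- n_up + n_down + n_unchanged + n_excluded
  usable <- chrom_length - 2 * cfg$margin
  slots_per_chrom <- if (usable < 0) 0 else floor(usable / cfg$spacing) + 1
  if (slots_per_chrom * n_chromosomes < n_genes) {
    stop("genome too small: ", n_genes, " genes requested but only ",
         slots_per_chrom * n_chromosomes, " TSS slots available at spacing ",
         cfg$spacing, " bp")
  }
  cfg$slots_per_chrom <- slots_per_chrom
  cfg$n_genes <- n_genes
  structure(cfg, class = "sim_config")
}

# run expr with a private RNG state seeded at `seed`; the caller's global
# RNG state is untouched
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stage_seed <- function(cfg, stage) {
  offs <- c(genes = 0L, deg = 500009L, tags = 1000003L)
  (cfg$seed + offs[[stage]]) %% .Machine$integer.max
}

#' Simulate the toy genome and gene annotation
#'
#' Places `n_genes` genes at randomly chosen TSS slots (grid spacing
#' `2 * flank_used + guard`, see [simulation_config()]), with random
#' strands and uniform gene lengths, and assigns latent group labels
#' (`up`, `down`, `unchanged`, `excluded`) uniformly at random over genes.
#' Deterministic given the configuration seed.
#'
#' @param config A `sim_config`.
#' @return A list: `layout` (`Seqinfo`), `annotation` (stranded `GRanges`
#'   with `gene_id`), `labels` (character vector named by gene id).
#' @export
simulate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.stage_seed(config, "genes"), {
    layout <- genome_layout(paste0("chr", seq_len(config$n_chromosomes)),
                            rep(config$chrom_length, config$n_chromosomes))
    slot_pos <- config$margin + config$spacing *
      (seq_len(config$slots_per_chrom) - 1)
    all_chrom <- rep(seqnames(layout), each = config$slots_per_chrom)
    all_pos <- rep(slot_pos, times = config$n_chromosomes)
    pick <- sort(sample.int(length(all_pos), config$n_genes))
    chrom <- all_chrom[pick]
    tss <- all_pos[pick]  # 1-based TSS position
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    len <- sample(seq(config$gene_length_range[1],
                      config$gene_length_range[2]),
                  config$n_genes, replace = TRUE)
    start <- ifelse(strand == "+", tss, tss - len + 1)
    end <- ifelse(strand == "+", tss + len - 1, tss)
    gene_id <- sprintf("gene_%04d", seq_len(config$n_genes))
    ann <- GRanges(chrom, IRanges(start, end), strand = strand,
                   gene_id = gene_id)
    seqinfo(ann) <- layout
    labels <- sample(rep(c("up", "down", "unchanged", "excluded"),
                         times = c(config$n_up, config$n_down,
                                   config$n_unchanged, config$n_excluded)))
    names(labels) <- gene_id
    list(layout = layout, annotation = ann, labels = labels)
  })
}

#' Simulate a DESeq2-style results table with known group structure
#'
#' Draws per-gene statistics so that [classify_genes()] at its defaults
#' recovers the planted labels exactly: up-regulated genes get
#' `padj ~ U(0, 0.04)` and a positive log2 fold change from N(2, 0.5)
#' truncated above 0.5; down-regulated genes the mirrored negative;
#' unchanged genes `padj ~ U(0.2, 1)` with `baseMean > 1`; excluded genes
#' `padj ~ U(0.2, 1)` with `baseMean <= 1`.
#'
#' @param config A `sim_config`.
#' @param labels Named group labels from [simulate_genes()].
#' @return A `data.frame` with columns `gene_id`, `baseMean`,
#'   `log2FoldChange`, `pvalue`, `padj`.
#' @export
simulate_deg_table <- function(config, labels) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.stage_seed(config, "deg"), {
    n <- length(labels)
    baseMean <- 10^runif(n, 0.05, 3)           # expressed: baseMean > 1.1
    lfc <- rnorm(n, 0, 0.2)
    padj <- runif(n, 0.2, 1)
    # truncated normal |lfc| > 0.5 via inverse-CDF on the upper tail
    trunc_pos <- function(k) qnorm(runif(k, pnorm((0.5 - 2) / 0.5), 1)) * 0.5 + 2
    is_up <- labels == "up"; is_down <- labels == "down"
    is_exc <- labels == "excluded"
    lfc[is_up] <- trunc_pos(sum(is_up))
    lfc[is_down] <- -trunc_pos(sum(is_down))
    padj[is_up | is_down] <- runif(sum(is_up | is_down), 0, 0.04)
    baseMean[is_exc] <- runif(sum(is_exc), 0, 0.99)
    data.frame(gene_id = names(labels), baseMean = baseMean,
               log2FoldChange = lfc,
               pvalue = padj * runif(n, 0.2, 1), padj = padj,
               stringsAsFactors = FALSE)
  })
}

#' Simulate ChIP tags with planted, group-biased binding sites
#'
#' Each gene receives a planted site with its group's `p_bind`
#' probability. A planted site's centre is the TSS plus N(0,
#' `site_jitter_sd`) noise, clipped into the gene's flank window;
#' `tags_per_site` tags are emitted with 5' positions N(centre,
#' `tag_jitter_sd`) and random strands. Background tags are uniform over
#' the genome at `background_tag_rate` per kb (Poisson total). The 5'
#' position is the planted quantity, matching the caller's default
#' counting mode. Deterministic given the configuration seed.
#'
#' @param config A `sim_config`.
#' @param genes Output of [simulate_genes()].
#' @return A list: `tags` (a `GRanges` tag set) and `truth` (a
#'   `data.frame` per gene: `gene_id`, `group`, `chrom`, `tss`, `bound`,
#'   `site_center`, `site_tags`; positions 1-based).
#' @export
simulate_tags <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.stage_seed(config, "tags"), {
    ann <- genes$annotation
    labels <- genes$labels
    layout <- genes$layout
    L <- config$chrom_length
    tss_gr <- extract_tss(ann)
    tss <- start(tss_gr)[match(names(labels), mcols(tss_gr)$gene_id)]
    chrom <- as.character(seqnames(ann))[match(names(labels),
                                               mcols(ann)$gene_id)]
    p <- ifelse(labels == "excluded", 0, config$p_bind[labels])
    bound <- runif(length(labels)) < p
    center <- rep(NA_real_, length(labels))
    if (any(bound)) {
      raw <- tss[bound] + round(rnorm(sum(bound), 0, config$site_jitter_sd))
      lo <- pmax(1, tss[bound] - config$flank_used)
      hi <- pmin(L, tss[bound] + config$flank_used)
      center[bound] <- pmin(pmax(raw, lo), hi)
    }
    site_tags <- .emit_tags(rep(chrom[bound], each = config$tags_per_site),
                            rep(center[bound], each = config$tags_per_site) +
                              round(rnorm(sum(bound) * config$tags_per_site,
                                          0, config$tag_jitter_sd)),
                            config, layout)
    n_bg <- rpois(1, config$background_tag_rate *
                    config$n_chromosomes * L / 1000)
    bg_chrom <- sample(seqnames(layout), n_bg, replace = TRUE)
    bg_pos <- floor(runif(n_bg, 1, L + 1))
    bg_tags <- .emit_tags(bg_chrom, bg_pos, config, layout)
    tags <- c(site_tags, bg_tags)
    truth <- data.frame(gene_id = names(labels), group = unname(labels),
                        chrom = chrom, tss = tss, bound = bound,
                        site_center = center,
                        site_tags = ifelse(bound, config$tags_per_site, 0L),
                        stringsAsFactors = FALSE)
    list(tags = tags, truth = truth)
  })
}

# construct tag intervals from 5' positions: plus-strand tags extend right,
# minus-strand tags extend left; the 5' base itself is never clipped away
.emit_tags <- function(chrom, pos5, config, layout) {
  n <- length(pos5)
  if (n == 0) {
    return(GRanges(seqinfo = layout))
  }
  chrom <- as.character(chrom)
  L <- seqlengths(layout)[chrom]
  pos5 <- pmin(pmax(pos5, 1), L)
  st <- sample(c("+", "-"), n, replace = TRUE)
  len <- config$tag_length
  start <- ifelse(st == "+", pos5, pmax(1, pos5 - len + 1))
  end <- ifelse(st == "+", pmin(L, pos5 + len - 1), pos5)
  GRanges(factor(chrom, levels = seqnames(layout)), IRanges(start, end),
          strand = st, seqinfo = layout)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Generates a complete synthetic dataset, then runs every analysis stage:
#' peak calling on the simulated tags, gene classification on the
#' simulated DE table, TSS-window construction at each requested flank,
#' window-peak overlap, and the group enrichment report — and evaluates
#' planted-site recovery (recall: fraction of planted site centres covered
#' by a called peak; precision: fraction of called peaks containing a
#' planted centre).
#'
#' @param config A `sim_config`.
#' @param flanks Flank sizes (bp) at which to run the enrichment analysis
#'   (default: the configuration's `flank_used`).
#' @param alternative Sidedness for the Z-tests (see [run_enrichment()]).
#' @return A list of class `sim_result`: `config`, `layout`, `annotation`,
#'   `labels`, `deg`, `tags`, `truth`, `peaks`, `peak_summary`, `groups`,
#'   `enrichment` (named list, one `enrichment_result` per flank),
#'   `recall`, `precision`.
#' @export
run_full_simulation <- function(config, flanks = config$flank_used,
                                alternative = "two.sided") {
  genes <- simulate_genes(config)
  deg <- simulate_deg_table(config, genes$labels)
  tg <- simulate_tags(config, genes)
  bins <- make_bins(genes$layout, config$bin_size, config$step)
  counted <- count_tags(bins, tg$tags, mode = "five_prime_start")
  peaks <- call_peaks(counted, threshold = config$threshold)
  groups <- classify_genes(deg)
  tss <- extract_tss(genes$annotation)
  enrichment <- lapply(flanks, function(fl) {
    win <- build_windows(tss, fl, genes$layout)
    flags <- gene_overlaps_peaks(win, peaks)
    run_enrichment(groups, flags, alternative = alternative)
  })
  names(enrichment) <- paste0("flank_", flanks)
  centers <- tg$truth$site_center[tg$truth$bound]
  if (length(centers)) {
    cgr <- GRanges(tg$truth$chrom[tg$truth$bound],
                   IRanges(centers, width = 1L))
    recall <- mean(overlapsAny(cgr, peaks))
    precision <- if (length(peaks)) mean(overlapsAny(peaks, cgr)) else NA_real_
  } else {
    recall <- NA_real_
    precision <- if (length(peaks)) 0 else NA_real_
  }
  n <- mcols(counted)$tag_count
  structure(list(
    config = config, layout = genes$layout, annotation = genes$annotation,
    labels = genes$labels, deg = deg, tags = tg$tags, truth = tg$truth,
    peaks = peaks,
    peak_summary = list(n_tags = length(tg$tags), bins_total = length(bins),
                        bins_passing = sum(n > config$threshold),
                        n_peaks = length(peaks),
                        bases_covered = covered_bases(peaks)),
    groups = groups, enrichment = enrichment,
    recall = recall, precision = precision), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Synthetic integration-analysis run (seed ", x$config$seed, ")\n",
      sep = "")
  cat(sprintf("  tags: %d  peaks: %d  planted-site recall: %s  precision: %s\n",
              x$peak_summary$n_tags, x$peak_summary$n_peaks,
              format(x$recall), format(x$precision)))
  for (nm in names(x$enrichment)) {
    cat("\n[", nm, "]\n", sep = "")
    print(x$enrichment[[nm]])
  }
  invisible(x)
}

#' Write the simulated dataset to disk
#'
#' Emits the standard input files for the pipeline: `genome.chrom.sizes`,
#' `genes.bed` (BED6, gene id in the name column), `tags.bed`, `deg.tsv`
#' and `truth.json`. Byte-identical across runs with the same
#' configuration.
#'
#' @param config A `sim_config`.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a named vector of the file paths.
#' @export
write_simulation <- function(config, outdir) {
  genes <- simulate_genes(config)
  deg <- simulate_deg_table(config, genes$labels)
  tg <- simulate_tags(config, genes)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.chrom.sizes"),
             genes = file.path(outdir, "genes.bed"),
             tags = file.path(outdir, "tags.bed"),
             deg = file.path(outdir, "deg.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_chrom_sizes(genes$layout, paths["genome"])
  ann <- genes$annotation
  mcols(ann)$name <- mcols(ann)$gene_id
  mcols(ann)$gene_id <- NULL
  write_bed(ann, paths["genes"])
  write_bed(tg$tags, paths["tags"])
  write.table(deg, paths["deg"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(config)[setdiff(names(config),
                                          c("slots_per_chrom", "n_genes"))],
         genes = tg$truth),
    paths["truth"], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
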