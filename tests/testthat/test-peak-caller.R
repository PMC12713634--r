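test_that("make_bins enumerates the sliding grid with truncated ends", {
  layout <- genome_layout("chr1", 2000)
  expect_equal(gr_to_df(make_bins(layout, 1000, 500)),
               data.frame(chrom = "chr1",
                          start0 = c(0, 500, 1000, 1500),
                          end0 = c(1000, 1500, 2000, 2000)))
  expect_equal(gr_to_df(make_bins(genome_layout("c", 800), 1000, 500)),
               data.frame(chrom = "c", start0 = c(0, 500), end0 = c(800, 800)))
  expect_equal(gr_to_df(make_bins(genome_layout("c", 500), 1000, 500)),
               data.frame(chrom = "c", start0 = 0, end0 = 500))
  expect_error(make_bins(layout, 100, 200), "step")
})

test_that("count_tags five_prime_start counts a tag in each bin holding its 5' end", {
  layout <- genome_layout("chr1", 2000)
  bins <- make_bins(layout, 1000, 500)
  tag <- df_to_gr(data.frame(chrom = "chr1", start0 = 600, end0 = 636,
                             strand = "+"), layout)
  counted <- count_tags(bins, tag, mode = "five_prime_start")
  expect_equal(counted$tag_count, c(1L, 1L, 0L, 0L))
  # minus-strand 5' end is the last base
  tagm <- df_to_gr(data.frame(chrom = "chr1", start0 = 600, end0 = 1200,
                              strand = "-"), layout)
  expect_equal(count_tags(bins, tagm)$tag_count, c(0L, 1L, 1L, 0L))
})

test_that("count_tags any_overlap counts every bin overlapped by >= 1 bp", {
  layout <- genome_layout("chr1", 2000)
  bins <- make_bins(layout, 1000, 500)
  tag <- df_to_gr(data.frame(chrom = "chr1", start0 = 990, end0 = 1010,
                             strand = "+"), layout)
  expect_equal(count_tags(bins, tag, mode = "any_overlap")$tag_count,
               c(1L, 1L, 1L, 0L))
})

test_that("tag counting matches the nested-loop oracle on random instances", {
  for (seed in 1:5) {
    inst <- random_instance(seed)
    bins <- make_bins(inst$layout, inst$bin_size, inst$step)
    tags <- df_to_gr(inst$tags, inst$layout)
    for (mode in c("five_prime_start", "any_overlap")) {
      got <- count_tags(bins, tags, mode = mode)$tag_count
      want <- oracle_count_tags(gr_to_df(bins), inst$tags, mode)
      expect_equal(got, want)
    }
  }
})

test_that("5' count conservation: each tag lands in a predictable number of bins", {
  # with step dividing bin_size and the 5' end >= bin_size - step from the
  # chromosome start (and not in the last truncated stretch), a tag is
  # counted in exactly bin_size/step bins
  layout <- genome_layout("chr1", 100000)
  bins <- make_bins(layout, 1000, 500)
  set.seed(42)
  p0 <- sample(1000:95000, 500, replace = TRUE)
  tags <- df_to_gr(data.frame(chrom = "chr1", start0 = p0, end0 = p0 + 36,
                              strand = "+"), layout)
  counted <- count_tags(bins, tags)
  expect_equal(sum(counted$tag_count), length(tags) * 2L)
})

test_that("call_peaks thresholds strictly and merges passing bins", {
  layout <- genome_layout("chr1", 2000)
  bins <- make_bins(layout, 1000, 500)
  S4Vectors::mcols(bins)$tag_count <- c(600L, 700L, 10L, 0L)
  expect_equal(gr_to_df(call_peaks(bins, 500)),
               data.frame(chrom = "chr1", start0 = 0, end0 = 1500))
  # nothing passes
  S4Vectors::mcols(bins)$tag_count <- c(10L, 20L, 0L, 5L)
  expect_length(call_peaks(bins, 500), 0)
  # exact-threshold bin is excluded under strict >, included under >=
  S4Vectors::mcols(bins)$tag_count <- c(500L, 0L, 0L, 0L)
  expect_length(call_peaks(bins, 500, strict = TRUE), 0)
  expect_length(call_peaks(bins, 500, strict = FALSE), 1)
  expect_error(call_peaks(bins, -1), "non-negative")
})

test_that("peak calling equals the brute-force oracle on random instances", {
  for (seed in 1:10) {
    inst <- random_instance(seed + 100)
    tags <- df_to_gr(inst$tags, inst$layout)
    counted <- count_tags(make_bins(inst$layout, inst$bin_size, inst$step),
                          tags)
    got <- gr_to_df(call_peaks(counted, inst$threshold))
    want <- oracle_call_peaks(inst$tags, inst$lens, inst$bin_size,
                              inst$step, inst$threshold)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("raising the threshold never enlarges the peak set", {
  inst <- random_instance(7)
  counted <- count_tags(make_bins(inst$layout, inst$bin_size, inst$step),
                        df_to_gr(inst$tags, inst$layout))
  prev <- call_peaks(counted, 0)
  for (thr in 1:5) {
    cur <- call_peaks(counted, thr)
    # covered bases of cur must be a subset of prev's
    extra <- GenomicRanges::setdiff(cur, prev, ignore.strand = TRUE)
    expect_equal(sum(width(extra)), 0)
    prev <- cur
  }
})

test_that("run_peak_calling works end to end from files", {
  dir <- withr::local_tempdir()
  layout_path <- file.path(dir, "genome.chrom.sizes")
  writeLines("chr1\t2000", layout_path)
  tags_path <- file.path(dir, "tags.bed")
  # 600 tags at position 600: bins [0,1000) and [500,1500) pass at thr 500
  writeLines(rep("chr1\t600\t636", 600), tags_path)
  out <- file.path(dir, "peaks.bed")
  summary_path <- file.path(dir, "summary.json")
  res <- run_peak_calling(tags_path, layout_path, threshold = 500,
                          out = out, summary_path = summary_path)
  expect_identical(readLines(out), "chr1\t0\t1500")
  expect_equal(res$summary$bins_passing, 2L)
  expect_equal(res$summary$n_peaks, 1L)
  expect_equal(res$summary$bases_covered, 1500)
  js <- jsonlite::read_json(summary_path)
  expect_equal(js$n_tags, 600L)

  # empty tag file -> no peaks
  writeLines(character(0), tags_path)
  res0 <- run_peak_calling(tags_path, layout_path, out = out)
  expect_equal(res0$summary$bins_passing, 0L)
  expect_identical(readLines(out), character(0))
})

test_that("pooled replicates and deduplication behave as documented", {
  dir <- withr::local_tempdir()
  layout_path <- file.path(dir, "genome.chrom.sizes")
  writeLines("chr1\t2000", layout_path)
  rep1 <- file.path(dir, "rep1.bed")
  rep2 <- file.path(dir, "rep2.bed")
  writeLines(rep("chr1\t600\t636", 300), rep1)
  writeLines(rep("chr1\t600\t636", 300), rep2)
  pooled <- run_peak_calling(c(rep1, rep2), layout_path, threshold = 500)
  expect_equal(pooled$summary$n_tags, 600L)
  expect_equal(pooled$summary$n_peaks, 1L)
  dedup <- run_peak_calling(c(rep1, rep2), layout_path, threshold = 500,
                            dedup = TRUE)
  expect_equal(dedup$summary$n_tags, 1L)
  expect_equal(dedup$summary$n_peaks, 0L)
})
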