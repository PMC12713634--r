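toy_groups <- function() {
  deg <- data.frame(
    gene_id = c(paste0("a", 1:10), paste0("b", 1:10), paste0("c", 1:10)),
    baseMean = 10,
    log2FoldChange = rep(c(2, -2, 0), each = 10),
    pvalue = NA_real_,
    padj = rep(c(0.01, 0.01, 0.9), each = 10),
    stringsAsFactors = FALSE)
  classify_genes(deg)
}

toy_flags <- function() {
  flags <- c(rep(TRUE, 8), rep(FALSE, 2),   # A: 8/10
             rep(TRUE, 3), rep(FALSE, 7),   # B: 3/10
             rep(TRUE, 2), rep(FALSE, 8))   # C: 2/10
  names(flags) <- c(paste0("a", 1:10), paste0("b", 1:10), paste0("c", 1:10))
  flags
}

test_that("overlap_frequency computes per-group proportions", {
  freq <- overlap_frequency(toy_groups(), toy_flags())
  expect_equal(freq$proportion, c(0.8, 0.3, 0.2))
  expect_equal(freq$n_genes, c(10L, 10L, 10L))
})

test_that("overlap_frequency drops unannotated genes and flags empty groups", {
  flags <- toy_flags()
  freq <- overlap_frequency(toy_groups(), flags[-(1:5)])  # a1..a5 missing
  expect_equal(freq$n_genes[freq$group == "up"], 5L)
  expect_equal(attr(freq, "n_dropped")[["up"]], 5L)
  # no flags at all: zero denominators, NA proportions, no error
  freq0 <- overlap_frequency(toy_groups(), setNames(logical(0), character(0)))
  expect_true(all(is.na(freq0$proportion)))
})

test_that("two_proportion_z matches the closed form and the chi-square cross-check", {
  # closed form: pooled p = 0.2, se = sqrt(0.2*0.8*0.02), z = 0.2/se
  zt <- two_proportion_z(30, 100, 10, 100)
  expect_equal(zt$z, 0.2 / sqrt(0.2 * 0.8 * 0.02), tolerance = 1e-12)
  expect_equal(signif(zt$z, 5), 3.5355)
  expect_equal(zt$p_value, 2 * pnorm(-zt$z), tolerance = 1e-12)
  expect_equal(signif(zt$p_value, 2), 4.1e-4)
  # z^2 equals the uncorrected chi-square statistic of prop.test
  pt <- prop.test(c(30, 10), c(100, 100), correct = FALSE)
  expect_equal(zt$z^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(zt$p_value, pt$p.value, tolerance = 1e-10)
})

test_that("two_proportion_z agrees with a permutation null", {
  x1 <- 18; n1 <- 40; x2 <- 9; n2 <- 45
  zt <- two_proportion_z(x1, n1, x2, n2)
  set.seed(99)
  pool <- c(rep(1, x1 + x2), rep(0, n1 + n2 - x1 - x2))
  obs <- abs(x1 / n1 - x2 / n2)
  B <- 20000
  perm <- replicate(B, {
    lab <- sample(pool)
    abs(mean(lab[1:n1]) - mean(lab[(n1 + 1):(n1 + n2)]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(zt$p_value - p_perm), mc_err + 0.01)
})

test_that("two_proportion_z handles symmetry, degeneracy and bad input", {
  eq <- two_proportion_z(5, 20, 5, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  deg0 <- two_proportion_z(0, 50, 0, 50)
  expect_true(deg0$degenerate)
  expect_equal(deg0$z, 0)
  expect_equal(deg0$p_value, 1)
  deg1 <- two_proportion_z(50, 50, 50, 50)
  expect_true(deg1$degenerate)
  expect_error(two_proportion_z(1, 0, 1, 10), ">= 1")
  expect_error(two_proportion_z(11, 10, 1, 10), "exceed")
  # one-sided options
  g <- two_proportion_z(30, 100, 10, 100, alternative = "greater")
  expect_equal(g$p_value, pnorm(g$z, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("run_enrichment reports the three pairwise comparisons", {
  res <- run_enrichment(toy_groups(), toy_flags())
  expect_equal(res$tests$comparison,
               c("up_vs_unchanged", "down_vs_unchanged", "up_vs_down"))
  ref <- two_proportion_z(8, 10, 2, 10)
  expect_equal(res$tests$z[1], ref$z)
  expect_equal(res$tests$p_value[1], ref$p_value)
  # identical proportions give p = 1 everywhere
  same <- c(rep(c(TRUE, FALSE), each = 5), rep(c(TRUE, FALSE), each = 5),
            rep(c(TRUE, FALSE), each = 5))
  names(same) <- names(toy_flags())
  res_same <- run_enrichment(toy_groups(), same)
  expect_true(all(res_same$tests$p_value == 1))
  # Bonferroni multiplies by the number of tests, capped at 1
  res_bf <- run_enrichment(toy_groups(), toy_flags(), bonferroni = TRUE)
  expect_equal(res_bf$tests$p_value,
               pmin(1, res$tests$p_value * 3))
})

test_that("enrichment reports serialize to TSV and JSON", {
  res <- run_enrichment(toy_groups(), toy_flags())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_enrichment(res, tsv_path = tsv, json_path = js)
  expect_true(any(grepl("up_vs_unchanged", readLines(tsv))))
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$counts$proportion, c(0.8, 0.3, 0.2))
})

test_that("welch_t_test matches stats::t.test on fixed and random data", {
  x <- c(0.1, 0.2, 0.15, 0.18)
  y <- c(0.3, 0.35, 0.28, 0.4)
  got <- welch_t_test(x, y)
  ref <- t.test(x, y)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1), sd = 2)
    expect_equal(welch_t_test(a, b)$p_value, t.test(a, b)$p.value,
                 tolerance = 1e-10)
    expect_equal(welch_t_test(a, b, pooled = TRUE)$p_value,
                 t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-10)
  }

  ident <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
})

test_that("qpcr_zscore standardizes 2^-dCt rows exactly", {
  tab <- data.frame(
    gene = rep(c("HPRT1", "gA", "gB"), each = 4),
    sample = rep(paste0("s", 1:4), 3),
    ct = c(20, 20, 21, 21,          # reference
           25, 24, 27, 25,          # gA: dCt = 5, 4, 6, 4
           30, 30, 31, 31),         # gB: dCt = 10 in all -> constant
    stringsAsFactors = FALSE)
  z <- qpcr_zscore(tab, reference = "HPRT1")
  # hand computation for gA
  r <- 2^(-c(5, 4, 6, 4))
  expect_equal(unname(z["gA", ]), (r - mean(r)) / sd(r), tolerance = 1e-12)
  expect_lt(abs(mean(z["gA", ])), 1e-12)
  expect_equal(sd(z["gA", ]), 1, tolerance = 1e-12)
  # constant dCt row: zero variance, flagged, not divided
  expect_true(attr(z, "zero_variance")[["gB"]])
  expect_true(all(is.na(z["gB", ])))
})

test_that("qpcr_zscore validates the reference gene and completeness", {
  tab <- data.frame(gene = c("HPRT1", "gA", "gA"),
                    sample = c("s1", "s1", "s2"), ct = c(20, 25, 26),
                    stringsAsFactors = FALSE)
  expect_error(qpcr_zscore(tab, "HPRT1"), "missing in sample")
  tab2 <- rbind(tab, data.frame(gene = "HPRT1", sample = "s2", ct = 20))
  z <- qpcr_zscore(tab2, "HPRT1")
  expect_equal(dim(z), c(1L, 2L))
  expect_error(qpcr_zscore(tab2[-2, ], "HPRT1"), "every sample")
})

test_that("qPCR tables read from TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tsample\tct\tcondition", "HPRT1\ts1\t20\tctrl",
               "gA\ts1\t25\tctrl"), path)
  tab <- read_qpcr_table(path)
  expect_equal(tab$ct, c(20, 25))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tct", "g\t20"), bad)
  expect_error(read_qpcr_table(bad), "must have columns")
})
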