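write_cov <- function(lines) {
  path <- withr::local_tempfile(fileext = ".cov",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("coverage files parse with validation", {
  p <- write_cov("chr1\t100\t100\t80.0\t8\t2")
  loci <- read_coverage(p, "s1")
  expect_equal(loci$m, 8L)
  expect_equal(loci$u, 2L)
  expect_equal(loci$pos, 100L)

  p2 <- write_cov("chr1\t100\t100\t80.0\t5\t5")
  expect_error(read_coverage(p2), "inconsistent.*line 1")

  p3 <- write_cov(character(0))
  expect_equal(nrow(read_coverage(p3)), 0)

  p4 <- write_cov("chr1\t100\t100\t50.0")
  expect_error(read_coverage(p4), "malformed.*line 1")
})

toy_loci <- function(cov_matrix, m_frac = 0.8,
                     pos = NULL, chrom = NULL) {
  n <- nrow(cov_matrix)
  if (is.null(pos)) pos <- seq(100L, by = 50L, length.out = n)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  M <- round(cov_matrix * m_frac)
  cond <- stats::setNames(rep(c("A", "B"),
                              each = ncol(cov_matrix) / 2),
                          colnames(cov_matrix))
  cpg_matrix(chrom, pos, M, cov_matrix - M, cond)
}

test_that("low-coverage loci are dropped per the per-sample rule", {
  cov <- rbind(c(30, 28, 26, 27), c(30, 24, 40, 40), c(25, 25, 25, 25))
  colnames(cov) <- c("A1", "A2", "B1", "B2")
  loci <- toy_loci(cov)
  kept <- filter_low_coverage(loci, min_cov = 25)
  expect_equal(length(kept$pos), 2)    # row 2 has a 24
  expect_equal(length(filter_low_coverage(loci, min_cov = 0)$pos), 3)
  # pooled mode keeps row 2 (sum 134 >= 25)
  expect_equal(length(filter_low_coverage(loci, min_cov = 25,
                                          scope = "pooled")$pos), 3)
})

test_that("region chaining follows the 200-bp gap rule", {
  cov <- matrix(50, nrow = 3, ncol = 2,
                dimnames = list(NULL, c("A1", "B1")))
  loci <- toy_loci(cov, pos = c(100L, 250L, 500L))
  reg <- aggregate_regions(loci, max_gap = 200)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start, c(100L, 500L))
  expect_equal(reg$end, c(250L, 500L))
  expect_equal(reg$n_loci, c(2L, 1L))
  # region sums conserve locus counts
  expect_equal(colSums(attr(reg, "M")), colSums(loci$M))

  # same positions on different chromosomes stay apart
  loci2 <- toy_loci(cov, pos = c(100L, 100L, 150L),
                    chrom = c("chr1", "chr2", "chr2"))
  expect_equal(nrow(aggregate_regions(loci2)), 2)

  # max_gap = 0 gives singleton regions
  expect_equal(nrow(aggregate_regions(loci, max_gap = 0)), 3)

  # single locus
  single <- toy_loci(matrix(50, 1, 2,
                            dimnames = list(NULL, c("A1", "B1"))))
  expect_equal(nrow(aggregate_regions(single)), 1)
})

test_that("region methylation filter requires >75% of replicates at 50%", {
  make_regions <- function(frac_A, frac_B) {
    cov <- matrix(100L, nrow = 1, ncol = 8,
                  dimnames = list(NULL, c(paste0("A", 1:4),
                                          paste0("B", 1:4))))
    M <- matrix(as.integer(100 * c(frac_A, frac_B)), nrow = 1)
    colnames(M) <- colnames(cov)
    cond <- stats::setNames(rep(c("A", "B"), each = 4), colnames(cov))
    aggregate_regions(cpg_matrix(rep("chr1", 1), 100L, M, cov - M, cond))
  }
  keep <- filter_regions_by_methylation(
    make_regions(c(0.6, 0.7, 0.8, 0.9), c(0.1, 0.1, 0.1, 0.1)))
  expect_equal(nrow(keep), 1)  # 4/4 replicates of A above 50%
  drop <- filter_regions_by_methylation(
    make_regions(c(0.6, 0.4, 0.4, 0.4), c(0.6, 0.4, 0.4, 0.4)))
  expect_equal(nrow(drop), 0)  # 1/4 <= 75% in both conditions
  # 3/4 = 75% is not strictly greater
  edge <- filter_regions_by_methylation(
    make_regions(c(0.6, 0.6, 0.6, 0.4), c(0.1, 0.1, 0.1, 0.1)))
  expect_equal(nrow(edge), 0)
  ident <- filter_regions_by_methylation(
    make_regions(c(0.2, 0.2, 0.2, 0.2), c(0.2, 0.2, 0.2, 0.2)),
    min_meth = 0)
  expect_equal(nrow(ident), 1)
})

test_that("the binomial GLM LRT matches the G-test on pooled counts", {
  res <- binomial_glm_lrt(m = c(20, 20, 5, 5), t = rep(25, 4),
                          condition = c("A", "A", "B", "B"))
  g <- g_test_2x2(40, 50, 10, 50)
  expect_equal(res$lrt, g, tolerance = 1e-6)
  expect_equal(res$p, stats::pchisq(g, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(res$lrt, 38.549, tolerance = 1e-3)
  expect_true(res$converged)

  # matches stats::glm as an independent fitting route
  gl <- stats::glm(cbind(c(20, 20, 5, 5), c(5, 5, 20, 20)) ~
                     factor(c("A", "A", "B", "B")), family = binomial)
  expect_equal(res$lrt, gl$null.deviance - gl$deviance, tolerance = 1e-6)
  expect_equal(res$beta1, unname(stats::coef(gl)[2]), tolerance = 1e-5)

  # identical proportions: no effect
  res0 <- binomial_glm_lrt(c(10, 10, 10, 10), rep(20, 4),
                           c("A", "A", "B", "B"))
  expect_equal(res0$lrt, 0, tolerance = 1e-10)
  expect_equal(res0$p, 1, tolerance = 1e-6)

  # separation (all 0 vs all 1) stays finite via the proportion clamp
  sep <- binomial_glm_lrt(c(25, 25, 0, 0), rep(25, 4),
                          c("A", "A", "B", "B"))
  expect_true(is.finite(sep$lrt) && is.finite(sep$beta1))
  expect_true(sep$p < 1e-6)

  expect_error(binomial_glm_lrt(c(1, 2, 3), c(5, 5, 5), c("A", "B", "C")),
               "two conditions")
})

test_that("null LRT statistics follow chi-square with 1 df", {
  set.seed(31)
  n <- 1000
  lrt <- numeric(n)
  for (i in seq_len(n)) {
    t <- rep(50, 8)
    m <- rbinom(8, 50, 0.5)
    lrt[i] <- binomial_glm_lrt(m, t, rep(c("A", "B"), each = 4))$lrt
  }
  # discrete counts produce occasional tied LRT values; the KS tie
  # warning is immaterial at n = 1000
  ks <- suppressWarnings(stats::ks.test(lrt, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
  # type-I error at the raw p <= 0.05 stage is ~5%
  p <- stats::pchisq(lrt, 1, lower.tail = FALSE)
  expect_equal(mean(p <= 0.05), 0.05, tolerance = 0.4)
})

test_that("BH adjustment and the dual DMR threshold are literal", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(0.04, 5)), rep(0.04, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  set.seed(33)
  p_raw <- runif(20)
  adj <- adjust_pvalues(p_raw)
  expect_true(all(adj >= p_raw))  # adjusted never below raw

  expect_true(call_dmrs(p = 0.001, p_adjust = 0.005))
  expect_false(call_dmrs(p = 0.04, p_adjust = 0.02))
  expect_false(call_dmrs(p = 0.2, p_adjust = 0.3))
})

test_that("power rises with effect size on synthetic datasets", {
  sizes <- c(0.5, 1.5, 3)
  power <- vapply(seq_along(sizes), function(i) {
    gm <- generate_methylation_dataset(120, effect = sizes[i],
                                       frac_affected = 0.5,
                                       coverage = 50, seed = 40 + i)
    res <- methylation_pipeline(gm$loci)
    truth <- gm$truth[match(res$start, gm$truth$start), ]
    mean(res$is_dmr[truth$affected])
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[3], 0.9)
})

test_that("null datasets stay below the nominal discovery rate", {
  gm <- generate_methylation_dataset(1000, effect = 0, frac_affected = 0,
                                     coverage = 50, seed = 51)
  res <- methylation_pipeline(gm$loci)
  expect_lte(mean(res$is_dmr), 0.01)
})

test_that("the full pipeline runs from files and exports TSV and BED", {
  dir <- withr::local_tempdir()
  gm <- generate_methylation_dataset(40, effect = 2.5, frac_affected = 0.3,
                                     coverage = 60, seed = 61, dir = dir)
  loci <- read_methylation_samples(file.path(dir, "samples.tsv"))
  res <- methylation_pipeline(loci)
  tsv <- file.path(dir, "dmr.tsv")
  bed <- file.path(dir, "dmr.bed")
  write_dmr_results(res, tsv, bed)
  back <- data.table::fread(tsv)
  expect_equal(nrow(back), nrow(res))
  if (sum(res$is_dmr) > 0) {
    bed_dt <- data.table::fread(bed, header = FALSE)
    expect_equal(nrow(bed_dt), sum(res$is_dmr))
    # 0-based half-open conversion
    expect_equal(bed_dt$V2, res$start[res$is_dmr] - 1L)
    expect_equal(bed_dt$V3, res$end[res$is_dmr])
  }
  # below-threshold coverage loci vanish
  low <- filter_low_coverage(loci, min_cov = 1000)
  expect_equal(length(low$pos), 0)
})
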