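sl1 <- c(chr1 = 30000)

test_that("coverage_from_reads conserves fragment mass and is linear", {
  reads <- tibble::tibble(chrom = "chr1", start = 100L, end = 150L,
                          strand = "+")
  cov <- coverage_from_reads(reads, sl1)
  expect_equal(sum(cov$plus$chr1), 50)
  expect_equal(sum(cov$plus$chr1 > 0), 50)
  expect_equal(sum(cov$minus$chr1), 0)
  # two identical reads double the coverage everywhere
  cov2 <- coverage_from_reads(dplyr::bind_rows(reads, reads), sl1)
  expect_true(all(cov2$plus$chr1 == 2 * cov$plus$chr1))
  # empty input: all-zero coverage
  cov0 <- coverage_from_reads(reads[0, ], sl1)
  expect_equal(sum(cov0$plus$chr1) + sum(cov0$minus$chr1), 0)
  # mass conservation on random read sets
  set.seed(1)
  r <- tibble::tibble(chrom = "chr1",
                      start = sample(0:29000, 300, replace = TRUE),
                      strand = sample(c("+", "-"), 300, replace = TRUE))
  r$end <- r$start + sample(20:150, 300, replace = TRUE)
  covr <- coverage_from_reads(r, sl1)
  expect_equal(sum(covr$plus$chr1), sum((r$end - r$start)[r$strand == "+"]))
  expect_equal(sum(covr$minus$chr1), sum((r$end - r$start)[r$strand == "-"]))
})

test_that("coverage_from_reads rejects out-of-bounds records", {
  bad <- tibble::tibble(chrom = "chr1", start = 29990L, end = 30010L,
                        strand = "+")
  expect_error(coverage_from_reads(bad, sl1), "29990")
  expect_error(coverage_from_reads(
    tibble::tibble(chrom = "chrX", start = 1L, end = 2L, strand = "+"), sl1),
    "chrX")
})

test_that("binned signal reproduces constant coverage and zero baselines", {
  reads <- tiling_reads("chr1", 0, 30000, "+", depth = 3)
  cov <- coverage_from_reads(reads, sl1)
  anch <- tibble::tibble(region_id = "r1", chrom = "chr1", tss = 15000L,
                         strand = "+")
  bs <- binned_promoter_signal(cov, anch, flank = 5000, bin = 100)
  expect_equal(dim(bs$sense), c(1, 100))
  # bin sum 300 -> log2(301) everywhere on sense, 0 on antisense
  expect_true(all(abs(bs$sense - log2(301)) < 1e-12))
  expect_true(all(bs$antisense == 0))
  # raw transform: row sum equals per-base coverage sum in the window
  bsr <- binned_promoter_signal(cov, anch, flank = 5000, bin = 100,
                                transform = "raw")
  expect_equal(sum(bsr$sense[1, ]), 3 * 10000)
})

test_that("mirroring the genome with flipped strands preserves both channels", {
  set.seed(2)
  L <- 30000L
  r <- tibble::tibble(chrom = "chr1",
                      start = sample(5000:25000, 400, replace = TRUE),
                      strand = sample(c("+", "-"), 400, replace = TRUE))
  r$end <- r$start + 100L
  anch <- tibble::tibble(region_id = c("a", "b"), chrom = "chr1",
                         tss = c(12000L, 20000L), strand = c("+", "-"))
  bs <- binned_promoter_signal(coverage_from_reads(r, sl1), anch)
  # reflect every read and anchor through the chromosome midpoint with
  # flipped strands: sense/antisense matrices must be reproduced exactly
  mirrored <- tibble::tibble(chrom = "chr1", start = L - r$end,
                             end = L - r$start,
                             strand = ifelse(r$strand == "+", "-", "+"))
  anch_m <- tibble::tibble(region_id = anch$region_id, chrom = "chr1",
                           tss = L - 1L - anch$tss,
                           strand = ifelse(anch$strand == "+", "-", "+"))
  bs2 <- binned_promoter_signal(coverage_from_reads(mirrored, sl1), anch_m)
  expect_equal(bs2$sense, bs$sense)
  expect_equal(bs2$antisense, bs$antisense)
  # flipping twice returns the original matrices
  bs3 <- binned_promoter_signal(
    coverage_from_reads(flip_reads(flip_reads(r)), sl1), anch)
  expect_identical(bs3$sense, bs$sense)
  expect_identical(bs3$antisense, bs$antisense)
})

test_that("minus-strand anchors are orientation-flipped (column 1 upstream)", {
  # one plus-strand read upstream of a minus-strand anchor (i.e. to its right)
  r <- tibble::tibble(chrom = "chr1", start = 15220L, end = 15300L,
                      strand = "+")
  anch <- tibble::tibble(region_id = "m", chrom = "chr1", tss = 15000L,
                         strand = "-")
  bs <- binned_promoter_signal(coverage_from_reads(r, sl1), anch,
                               transform = "raw")
  hit_bins <- which(bs$antisense[1, ] > 0)
  # read sits 220-300 bp upstream: the (200, 300] upstream bin, column 48
  expect_equal(hit_bins, 48L)
  expect_equal(sum(bs$antisense[1, ]), 80)
})

test_that("out-of-window anchors are dropped with a warning", {
  cov <- coverage_from_reads(
    tibble::tibble(chrom = "chr1", start = 1L, end = 2L, strand = "+"), sl1)
  anch <- tibble::tibble(region_id = c("edge", "ok"), chrom = "chr1",
                         tss = c(3000L, 15000L), strand = "+")
  expect_warning(bs <- binned_promoter_signal(cov, anch), "dropping 1")
  expect_equal(rownames(bs$sense), "ok")
  expect_error(
    suppressWarnings(binned_promoter_signal(cov, anch[1, ])), "usable")
})

test_that("antisense_score sums the most-upstream bins", {
  m <- matrix(0, 2, 100)
  m[1, 1:50] <- 1
  m[2, 1] <- 2
  expect_equal(unname(antisense_score(m, 50)), c(50, 2))
  expect_equal(unname(antisense_score(matrix(0, 1, 100), 50)), 0)
})

test_that("meta_profile averages oriented rows", {
  r <- dplyr::bind_rows(
    tiling_reads("chr1", 10000, 14000, "+"),   # downstream of anchor a only
    tiling_reads("chr1", 18000, 22000, "+")
  )
  cov <- coverage_from_reads(r, sl1)
  one <- tibble::tibble(region_id = "a", chrom = "chr1", tss = 10000L,
                        strand = "+")
  two <- dplyr::bind_rows(one,
    tibble::tibble(region_id = "b", chrom = "chr1", tss = 20000L,
                   strand = "+"))
  p1 <- meta_profile(cov, one)
  bs <- binned_promoter_signal(cov, one, transform = "raw")
  expect_equal(p1$mean, unname(bs$sense[1, ]))
  # n identical regions give the single-region profile
  rep3 <- dplyr::bind_rows(one, one, one)
  rep3$region_id <- c("a1", "a2", "a3")
  expect_equal(meta_profile(cov, rep3)$mean, p1$mean)
  # mean of two differing rows
  p2 <- meta_profile(cov, two)
  b2 <- binned_promoter_signal(cov, two, transform = "raw")
  expect_equal(p2$mean, unname(colMeans(b2$sense)))
  expect_equal(p2$n_regions[1], 2)
})

test_that("rescaled_region_profile rescales, orients and averages", {
  r <- tiling_reads("chr1", 10000, 13000, "+", depth = 3)
  cov <- coverage_from_reads(r, sl1)
  reg <- tibble::tibble(chrom = "chr1", start = 10000L, end = 13000L,
                        strand = "+")
  p <- rescaled_region_profile(cov, reg, n_bins = 100)
  expect_true(all(abs(p$mean - 3) < 1e-12))
  # ramp: coverage depth grows along the region -> linear bin means
  ramp <- dplyr::bind_rows(lapply(1:10, function(d) {
    tiling_reads("chr1", 10000 + (d - 1) * 300, 10000 + d * 300, "+",
                 depth = d)
  }))
  covr <- coverage_from_reads(ramp, sl1)
  pr <- rescaled_region_profile(covr, reg, n_bins = 10)
  expect_equal(pr$mean, as.numeric(1:10))
  # minus-strand region: profile reversed relative to genomic order
  regm <- reg; regm$strand <- "-"
  pm <- rescaled_region_profile(covr, regm, n_bins = 10, channel = "opposite")
  expect_equal(pm$mean, as.numeric(10:1))
  # short regions are dropped with a warning
  shrt <- tibble::tibble(chrom = "chr1", start = 10L, end = 50L, strand = "+")
  expect_warning(rescaled_region_profile(cov, dplyr::bind_rows(reg, shrt)),
                 "shorter")
})

test_that("feature_fraction_profile counts anchors inside features", {
  anch <- tibble::tibble(region_id = c("a", "b"), chrom = "chr1",
                         tss = c(10000L, 20000L), strand = "+")
  all_feat <- tibble::tibble(chrom = "chr1", start = 0L, end = 30000L)
  p <- feature_fraction_profile(all_feat, anch, flank = 1000, step = 100)
  expect_true(all(p$mean == 1))
  none <- tibble::tibble(chrom = "chr1", start = integer(), end = integer())
  p0 <- feature_fraction_profile(none, anch, flank = 1000, step = 100)
  expect_true(all(p0$mean == 0))
  # feature covering exactly one of two anchors at position 0
  half <- tibble::tibble(chrom = "chr1", start = 10000L, end = 10001L)
  ph <- feature_fraction_profile(half, anch, flank = 1000, step = 100)
  expect_equal(ph$mean[ph$position == 0], 0.5)
  expect_true(all(ph$mean >= 0 & ph$mean <= 1))
})
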