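dna <- function(...) Biostrings::DNAStringSet(c(...))

test_that("gc_content_profile counts G+C per oriented bin", {
  g <- dna(chr1 = strrep("GC", 10000))
  anch <- tibble::tibble(region_id = "a", chrom = "chr1", tss = 10000L,
                         strand = "+")
  expect_true(all(gc_content_profile(g, anch, flank = 2000)$mean == 1))
  g2 <- dna(chr1 = strrep("AT", 10000))
  expect_true(all(gc_content_profile(g2, anch, flank = 2000)$mean == 0))
  g3 <- dna(chr1 = strrep("ACGT", 5000))
  expect_true(all(abs(gc_content_profile(g3, anch, flank = 2000)$mean - 0.5)
                  < 1e-12))
})

test_that("gc_skew computes (G - C) / (G + C) with an NA sentinel", {
  expect_equal(gc_skew(c("GGGG", "GCGC", "GGC")), c(1, 0, 1 / 3))
  expect_true(is.na(gc_skew("AATT")))
  # reverse complement negates the skew
  set.seed(14)
  for (rep in 1:50) {
    s <- paste0(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- gc_skew(s); b <- gc_skew(rc)
    if (is.na(a)) expect_true(is.na(b)) else expect_equal(b, -a)
  }
})

test_that("gc_skew_profile reads in gene orientation and is involutive", {
  set.seed(15)
  g <- dna(chr1 = paste0(sample(c("A", "C", "G", "T"), 30000, TRUE,
                                prob = c(0.29, 0.21, 0.21, 0.29)),
                         collapse = ""))
  anch <- tibble::tibble(region_id = c("p", "m"), chrom = "chr1",
                         tss = c(10000L, 20000L), strand = c("+", "-"))
  p <- gc_skew_profile(g, anch, flank = 2000, bin = 100)
  # involution: reverse-complementing the genome and flipping the anchors
  # reproduces the profile
  L <- 30000L
  grc <- dna(chr1 = as.character(Biostrings::reverseComplement(g[[1]])))
  anch_rc <- tibble::tibble(region_id = c("p", "m"), chrom = "chr1",
                            tss = L - 1L - anch$tss,
                            strand = c("-", "+"))
  p2 <- gc_skew_profile(grc, anch_rc, flank = 2000, bin = 100)
  expect_equal(p2$mean, p$mean, tolerance = 1e-12)
  # skew-free random genome: profile centred on zero (2 anchors only, so
  # individual 100 bp bins stay noisy)
  expect_lt(max(abs(p$mean)), 0.5)
  expect_lt(abs(mean(p$mean)), 0.06)
})

test_that("planted GC skew is recovered from the simulated genome", {
  cfg <- small_sim_config(seed = 21)
  sim <- simulate_genome(cfg)
  ann <- simulate_annotation(sim, cfg)
  genes <- ann$truth[ann$truth$kind == "gene", ]
  anch <- tibble::tibble(region_id = genes$gene_id, chrom = genes$chrom,
                         tss = genes$tss, strand = genes$strand)
  p <- gc_skew_profile(sim$genome, anch, flank = 1000, bin = 100)
  downstream <- p$mean[p$position > 0 & p$position < 500]
  # plateau level within the planting tolerance; individual bins are noisier
  expect_lt(abs(mean(downstream) - 0.3), 0.05)
  expect_true(all(abs(downstream - 0.3) < 0.15))
  # zero amplitude: no skew anywhere
  zero_amp <- c(luat_associated = 0, coding_coding = 0, unidirectional = 0)
  cfg0 <- sim_config(
    seed = 21,
    genome = list(n_chrom = 1L, chrom_length = 3e6, margin = 15000,
                  skew = list(downstream = zero_amp, upstream = zero_amp)),
    genes = list(n = 30L, mean_extra_gap = 30000)
  )
  sim0 <- simulate_genome(cfg0)
  p0 <- gc_skew_profile(sim0$genome, anch, flank = 1000, bin = 100)
  expect_lt(max(abs(p0$mean)), 0.1)
})

test_that("detect_cpg_islands flags CpG-dense sequence and nothing else", {
  s <- paste0(strrep("A", 1000), strrep("CG", 150), strrep("A", 1000))
  isl <- detect_cpg_islands(dna(chr1 = s))
  expect_equal(nrow(isl), 1)
  expect_gt(isl$obs_exp, 1.9)              # (CG)x150 has obs/exp near 1.99
  expect_true(isl$start <= 1000 + 200 && isl$end >= 1300 - 200 + 1)
  # poly-A only: no island
  expect_equal(nrow(detect_cpg_islands(dna(chr1 = strrep("A", 1000)))), 0)
  # reported islands re-satisfy both thresholds and the structure invariants
  set.seed(16)
  bg <- sample(c("A", "C", "G", "T"), 20000, TRUE)
  plant <- function(at, len) {
    tok <- ifelse(runif(len) < 0.3, "CG",
                  sample(c("G", "C", "A", "T"), len, TRUE,
                         prob = c(0.3, 0.3, 0.2, 0.2)))
    str <- substr(paste0(tok, collapse = ""), 1, len)
    bg[at:(at + len - 1)] <<- strsplit(str, "")[[1]]
  }
  plant(3000, 600); plant(9000, 400); plant(15000, 1000)
  isl2 <- detect_cpg_islands(dna(chr1 = paste0(bg, collapse = "")))
  expect_gte(nrow(isl2), 3)
  expect_true(all(isl2$gc >= 0.5))
  expect_true(all(isl2$obs_exp >= 0.6))
  expect_true(all(isl2$end - isl2$start >= 200))
  if (nrow(isl2) > 1) {
    expect_true(all(isl2$start[-1] >= isl2$end[-nrow(isl2)]))  # disjoint
  }
})

test_that("promoter_cpg_summary sums island lengths around the TSS", {
  genes <- tibble::tibble(region_id = c("g1", "g2"), chrom = "chr1",
                          tss = c(10000L, 50000L), strand = "+")
  islands <- tibble::tibble(
    chrom = "chr1",
    start = c(9700L, 10400L),        # [-300, 200) and [400, 800) around g1
    end = c(10200L, 10800L)
  )
  out <- promoter_cpg_summary(islands, genes)
  expect_equal(out$covered, c(TRUE, FALSE))
  expect_equal(out$total_island_bp, c(900L, 0L))
  # island straddling the window edge counts its full length by default
  edge <- tibble::tibble(chrom = "chr1", start = 10800L, end = 12000L)
  out2 <- promoter_cpg_summary(edge, genes)
  expect_equal(out2$total_island_bp[1], 1200L)
  out3 <- promoter_cpg_summary(edge, genes, clip = TRUE)
  expect_equal(out3$total_island_bp[1], 200L)   # clipped at TSS + 1000
})

test_that("pwm building, consensus and max-score scanning agree with brute force", {
  counts <- rbind(A = c(10, 0, 0, 8), C = c(0, 10, 0, 1),
                  G = c(0, 0, 10, 1), T = c(0, 0, 0, 0))
  pwm <- pwm_from_counts(counts, "toy")
  expect_equal(pwm_consensus(pwm), "ACGA")
  # planted consensus scores the column-max sum
  s <- paste0(strrep("T", 200), "ACGA", strrep("T", 296))
  g <- dna(chr1 = s)
  anchor <- tibble::tibble(region_id = "x", chrom = "chr1", tss = 250L,
                           strand = "+")
  sc <- pwm_max_score(g, anchor, pwm, window = 500)
  expect_equal(sc$max_score, pwm_consensus_score(pwm))
  # locality: content outside the window is irrelevant
  g2 <- dna(chr1 = paste0(strrep("G", 200), "ACGA", strrep("C", 296)))
  expect_equal(pwm_max_score(g2, anchor, pwm, window = 500)$max_score,
               sc$max_score)
  # all-N window scores the sentinel minimum (finite, very negative)
  gN <- dna(chr1 = strrep("N", 500))
  scN <- pwm_max_score(gN, anchor, pwm, window = 400)
  expect_lt(scN$max_score, 0)
  # brute-force oracle on random sequences
  set.seed(17)
  for (rep in 1:20) {
    seq1k <- paste0(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    m <- pwm$matrix
    code <- match(strsplit(seq1k, "")[[1]], c("A", "C", "G", "T"))
    brute <- max(vapply(1:(1000 - 4 + 1), function(i) {
      sum(vapply(1:4, function(j) m[code[i + j - 1], j], numeric(1)))
    }, numeric(1)))
    ganon <- dna(chr1 = seq1k)
    a <- tibble::tibble(region_id = "r", chrom = "chr1", tss = 500L,
                        strand = "+")
    expect_equal(pwm_max_score(ganon, a, pwm, window = 1000)$max_score, brute)
  }
})

test_that("read_jaspar parses the flat format", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MX0001.1 toybox",
    "A [ 10  0  0  8 ]",
    "C [  0 10  0  1 ]",
    "G [  0  0 10  1 ]",
    "T [  0  0  0  0 ]"
  ), path)
  pwm <- read_jaspar(path)
  expect_equal(pwm$motif_id, "MX0001.1")
  expect_equal(ncol(pwm$matrix), 4)
  expect_equal(pwm_consensus(pwm), "ACGA")
})

test_that("splice_site_accumulation steps where the first full site appears", {
  counts <- diag(4) * 10
  rownames(counts) <- c("A", "C", "G", "T")
  pwm <- pwm_from_counts(counts, "ACGT-motif")   # consensus ACGT, length 4
  thr <- pwm_consensus_score(pwm) - 0.01
  # every gene has the consensus at +10 (1-based) downstream of its TSS
  s <- paste0(strrep("T", 100), strrep("A", 9), "ACGT", strrep("T", 487))
  g <- dna(chr1 = s)
  genes <- tibble::tibble(region_id = "g1", chrom = "chr1", tss = 100L,
                          strand = "+")
  curve <- splice_site_accumulation(g, genes, pwm, span = 100,
                                    threshold = thr)
  # full site visible after 10 + 4 - 1 nucleotides
  expect_equal(curve$fraction[curve$x < 13], rep(0, 12))
  expect_true(all(curve$fraction[curve$x >= 13] == 1))
  # no hits anywhere
  gnone <- dna(chr1 = strrep("T", 700))
  c0 <- splice_site_accumulation(gnone, genes, pwm, span = 100,
                                 threshold = thr)
  expect_true(all(c0$fraction == 0))
  # monotone, bounded curves on random sequence
  set.seed(18)
  grand <- dna(chr1 = paste0(sample(c("A", "C", "G", "T"), 2000, TRUE),
                             collapse = ""))
  gs <- tibble::tibble(region_id = c("a", "b"), chrom = "chr1",
                       tss = c(300L, 900L), strand = c("+", "-"))
  cr <- splice_site_accumulation(grand, gs, pwm, span = 300, threshold = thr)
  expect_true(all(diff(cr$fraction) >= 0))
  expect_true(all(cr$fraction >= 0 & cr$fraction <= 1))
})
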