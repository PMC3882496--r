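test_that("simulated genome is reproducible and respects its GC target", {
  cfg <- sim_config(seed = 31,
                    genome = list(n_chrom = 1L, chrom_length = 4e5,
                                  margin = 12000),
                    genes = list(n = 6L, mean_extra_gap = 20000))
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(cfg)
  expect_identical(as.character(sim1$genome), as.character(sim2$genome))
  expect_equal(as.integer(Biostrings::width(sim1$genome)), 4e5)
  f <- Biostrings::letterFrequency(sim1$genome, c("G", "C"))
  expect_lt(abs(sum(f) / 4e5 - 0.42), 0.05)
  # different seed, different sequence
  sim3 <- simulate_genome(sim_config(seed = 32,
                                     genome = list(n_chrom = 1L,
                                                   chrom_length = 4e5,
                                                   margin = 12000),
                                     genes = list(n = 6L,
                                                  mean_extra_gap = 20000)))
  expect_false(identical(as.character(sim1$genome),
                         as.character(sim3$genome)))
})

test_that("planted CpG islands are recovered by the island caller", {
  # skew planting disabled so the islands stay intact for this check
  zero_amp <- c(luat_associated = 0, coding_coding = 0, unidirectional = 0)
  cfg <- sim_config(
    seed = 33,
    genome = list(n_chrom = 1L, chrom_length = 3e6, margin = 15000,
                  skew = list(downstream = zero_amp, upstream = zero_amp)),
    genes = list(n = 30L, mean_extra_gap = 30000)
  )
  sim <- simulate_genome(cfg)
  found <- detect_cpg_islands(sim$genome)
  planted <- sim$cpg_islands
  expect_gt(nrow(planted), 5)
  hit <- IRanges::countOverlaps(
    IRanges::IRanges(planted$start + 1, planted$end),
    IRanges::IRanges(found$start + 1, found$end)) > 0
  expect_gt(mean(hit), 0.9)
})

test_that("simulated annotation has the planted structure", {
  cfg <- small_sim_config(seed = 34)
  ann <- simulate_annotation(c(chr1 = 3e6), cfg)
  tx <- ann$transcripts
  truth <- ann$truth
  expect_equal(nrow(tx), 30)
  # head-to-head pairs: fraction 0.1 of 30 genes -> 1-2 pairs, TSS sep < 1500
  cc <- truth[truth$kind == "gene" & truth$class == "coding_coding", ]
  expect_equal(nrow(cc) %% 2, 0)
  expect_gt(nrow(cc), 0)
  for (i in seq(1, nrow(cc), by = 2)) {
    expect_true(abs(cc$tss[i] - cc$tss[i + 1]) < 1500)
    expect_false(cc$strand[i] == cc$strand[i + 1])
  }
  # non-pair genes have >= 5 kb clear upstream: the candidate filter keeps them
  cand <- select_candidate_promoters(tx, c(chr1 = 3e6))
  non_pair <- truth$gene_id[truth$kind == "gene" &
                              truth$class != "coding_coding"]
  expect_true(all(non_pair %in% cand$gene_id))
  # every planted LUAT lies on the antisense strand of its gene, upstream
  luat <- truth[truth$kind == "luat", ]
  genes <- truth[truth$kind == "gene", ]
  for (i in seq_len(nrow(luat))) {
    gene <- genes[genes$gene_id == luat$gene_id[i], ]
    expect_false(luat$strand[i] == gene$strand)
    expect_lte(luat$luat_offset[i], 0)
  }
  # first-exon medians follow the class configuration ordering
  fe <- first_exon_length(tx)
  cls <- truth$class[match(tx$gene_id, truth$gene_id)]
  expect_gt(median(fe[cls == "luat_associated"]), 150)
  # classify_gene_sets on truth-only (no reads -> nothing called) recovers
  # the planted unidirectional / coding-coding labels
  no_calls <- tibble::tibble(region_id = character(), gene_id = character(),
                             antisense_score = numeric(), called = logical())
  sets <- classify_gene_sets(cand, no_calls, tx)
  for (g in genes$gene_id) {
    want <- if (genes$class[genes$gene_id == g] == "coding_coding")
      "coding_coding" else "unidirectional"
    expect_equal(sets$label[sets$gene_id == g], want)
  }
})

test_that("zero genes requested gives an empty annotation", {
  cfg <- sim_config(seed = 35, genome = list(n_chrom = 1L, chrom_length = 1e5),
                    genes = list(n = 0L))
  ann <- simulate_annotation(c(chr1 = 1e5), cfg)
  expect_equal(nrow(ann$transcripts), 0)
  expect_equal(nrow(ann$truth), 0)
})

test_that("annotation errors when the genome cannot hold the genes", {
  cfg <- sim_config(seed = 36,
                    genome = list(n_chrom = 1L, chrom_length = 1e5),
                    genes = list(n = 50L))
  expect_error(simulate_annotation(c(chr1 = 1e5), cfg), "too small")
})

test_that("simulated reads have Poisson-consistent counts and are reproducible", {
  cfg <- small_sim_config(seed = 37)
  ann <- simulate_annotation(c(chr1 = 3e6), cfg)
  reads1 <- simulate_reads(ann, config = cfg)
  reads2 <- simulate_reads(ann, config = cfg)
  expect_identical(reads1, reads2)
  # expected fragment count: FPKM x exonic kb x library Mfrags
  tx <- ann$transcripts
  truth <- ann$truth
  lib_m <- cfg$expression$library_size / 1e6
  for (i in sample(seq_len(nrow(tx)), 5)) {
    tr <- truth[truth$entity_id == tx$transcript_id[i], ]
    mu <- tr$fpkm * tx$exonic_length[i] / 1000 * lib_m
    n_obs <- sum(reads1$origin == tr$entity_id)
    expect_lt(abs(n_obs - mu), 4 * sqrt(mu) + 5)
  }
  # fragments land inside their transcript, on its strand
  g1 <- tx[1, ]
  fr <- reads1[reads1$origin == g1$transcript_id, ]
  expect_true(all(fr$strand == g1$strand))
  expect_true(all(fr$start >= g1$start & fr$end <= g1$end))
  # zero retention: no sense fragment fully inside intron 1
  fi <- first_intron(tx)
  for (i in seq_len(nrow(fi))) {
    own <- reads1[reads1$origin == fi$transcript_id[i], ]
    inside <- own$start >= fi$start[i] & own$end <= fi$end[i]
    expect_equal(sum(inside), 0)
  }
})

test_that("planted intron retention fills the first intron proportionally", {
  cfg <- small_sim_config(
    seed = 38,
    genes = list(n = 20L),
    expression = list(retention = c(luat_associated = 0.25,
                                    coding_coding = 0.25,
                                    unidirectional = 0.25),
                      background_per_kb = 0,
                      gene_fpkm = list(meanlog = log(20), sdlog = 0.2)))
  ann <- simulate_annotation(c(chr1 = 3e6), cfg)
  reads <- simulate_reads(ann, config = cfg)
  feats <- feature_fpkm(reads, ann$transcripts, cfg$expression$library_size)
  i1 <- feats[feats$feature == "intron" & feats$index == 1, ]
  e1 <- feats[feats$feature == "exon" & feats$index == 1, ]
  shared <- intersect(i1$transcript_id, e1$transcript_id)
  ratio <- i1$fpkm[match(shared, i1$transcript_id)] /
    e1$fpkm[match(shared, e1$transcript_id)]
  # intron-1 signal near the 25% retention level of the exonic signal
  expect_gt(median(ratio), 0.12)
  expect_lt(median(ratio), 0.45)
})

test_that("multi-tissue simulation plants correlation and specificity", {
  cfg <- sim_config(seed = 39,
                    genome = list(n_chrom = 1L, chrom_length = 2e7),
                    genes = list(n = 150L, luat_fraction = 0.6,
                                 mean_extra_gap = 40000),
                    tissues = list(rho = 0.8))
  mt <- simulate_multitissue(cfg)
  expect_identical(mt$expr, simulate_multitissue(cfg)$expr)
  expect_equal(sum(mt$expr$kind == "luat"), 90)
  pc <- pair_correlation(mt$expr, mt$pairs, log2 = TRUE)
  expect_lt(abs(mean(pc$r) - 0.8), 0.05)
  # rho = 1: perfectly correlated pairs (log scale)
  cfg1 <- sim_config(seed = 40,
                     genome = list(n_chrom = 1L, chrom_length = 2e7),
                     genes = list(n = 40L, luat_fraction = 0.5,
                                  mean_extra_gap = 40000),
                     tissues = list(rho = 1))
  mt1 <- simulate_multitissue(cfg1)
  pc1 <- pair_correlation(mt1$expr, mt1$pairs, log2 = TRUE)
  expect_true(all(pc1$r > 0.999))
  expect_error(sim_config(tissues = list(rho = 1.2)), "rho")
  # planted tissue-specific genes score TS > 1 in their tissue
  ts <- tissue_specificity(mt$expr)
  spec <- mt$truth[!is.na(mt$truth$specific_tissue), ]
  hit <- vapply(seq_len(nrow(spec)), function(i) {
    row <- ts[ts$entity_id == spec$entity_id[i] &
                ts$condition == spec$specific_tissue[i], ]
    row$specific
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
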