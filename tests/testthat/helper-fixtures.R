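# Small builders shared across tests; everything is generated in code.

tx_row <- function(id, gene, chrom, strand, starts, ends, coding = TRUE) {
  tibble::tibble(
    transcript_id = id, gene_id = gene, chrom = chrom, strand = strand,
    exon_start = list(as.integer(starts)), exon_end = list(as.integer(ends)),
    is_coding = coding
  )
}

make_tx <- function(...) transcripts_tbl(dplyr::bind_rows(...))

# constant-coverage reads: `depth` stacked fragments tiling [from, to)
tiling_reads <- function(chrom, from, to, strand, depth = 1, width = 100L) {
  starts <- seq(from, to - width, by = width)
  tibble::tibble(
    chrom = chrom,
    start = rep(as.integer(starts), depth),
    end = rep(as.integer(starts + width), depth),
    strand = strand
  )
}

# flip every strand of a read set
flip_reads <- function(reads) {
  reads$strand <- ifelse(reads$strand == "+", "-", "+")
  reads
}

# brute-force type-7 quantile (independent of stats::quantile)
bf_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  q <- x[lo]
  if (lo < n) q <- q + (h - lo) * (x[lo + 1] - x[lo])
  q
}

# brute-force single-linkage gap clustering oracle for the merge/extend
# assembler: clusters fragments with linkage gap < max_gap (O(n^2)), keeps
# clusters holding a seed (5' end within seed_window of the TSS), and
# returns the span of the cluster whose seed lies closest to the TSS.
bf_merge_extend <- function(fragments, gene, seed_window = 1500,
                            min_len = 200, max_gap = 800) {
  fr <- fragments[(fragments$end - fragments$start) >= min_len, , drop = FALSE]
  n <- nrow(fr)
  if (n == 0) return(NULL)
  luat_strand <- if (gene$strand == "+") "-" else "+"
  five <- if (luat_strand == "-") fr$end - 1L else fr$start
  gap <- function(i, j) {
    max(fr$start[i], fr$start[j]) - min(fr$end[i], fr$end[j])
  }
  # transitive closure of the gap-below-max_gap relation
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cl[i] != cl[j] && gap(i, j) < max_gap) {
        cl[cl == cl[j]] <- cl[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  is_seed <- abs(five - gene$tss) <= seed_window
  if (!any(is_seed)) return(NULL)
  best <- cl[is_seed][which.min(abs(five - gene$tss)[is_seed])]
  members <- cl == best
  tibble::tibble(start = min(fr$start[members]), end = max(fr$end[members]),
                 strand = luat_strand)
}

# tiny default-shaped simulation scaled down for unit tests
small_sim_config <- function(seed = 3, genes = list(), expression = list(),
                             tissues = list()) {
  sim_config(
    seed = seed,
    genome = list(n_chrom = 1L, chrom_length = 3e6, margin = 15000),
    genes = utils::modifyList(list(n = 30L, mean_extra_gap = 30000), genes),
    expression = expression,
    tissues = tissues
  )
}
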