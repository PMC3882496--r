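#' GC content profile around anchors
#'
#' Mean fraction of G+C per oriented bin across anchors. `N` bases are
#' excluded from the denominator; a bin that is all-N contributes nothing for
#' that anchor.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param anchors Transcript table or anchor tibble.
#' @param flank Half-window in bp (default 5000).
#' @param bin Bin width in bp (default 100).
#' @return A `meta_profile` tibble (`position`, `mean`, `n_regions`).
#' @export
gc_content_profile <- function(genome, anchors, flank = 5000, bin = 100) {
  counts <- promoter_bin_base_counts(genome, anchors, flank, bin)
  gc <- counts$G + counts$C
  tot <- counts$A + counts$C + counts$G + counts$T
  frac <- gc / tot           # NaN where all-N
  new_meta_profile(bin_positions(flank, bin),
                   colMeans(frac, na.rm = TRUE), nrow(frac))
}

#' GC skew of a sequence
#'
#' `(#G - #C) / (#G + #C)`; `NA` when the sequence contains no G or C.
#'
#' @param seq Character vector of sequences (or a `DNAStringSet`).
#' @return Numeric vector in \[-1, 1\] (NA for G+C-free input).
#' @examples
#' gc_skew(c("GGGG", "GCGC", "GGC"))  # 1, 0, 1/3
#' @export
gc_skew <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(seq)
  f <- Biostrings::letterFrequency(seq, c("G", "C"))
  g <- f[, "G"]; c_ <- f[, "C"]
  ifelse(g + c_ == 0, NA_real_, (g - c_) / (g + c_))
}

#' GC skew profile around anchors
#'
#' Per oriented bin, the mean GC skew of the sense-strand (reading-direction)
#' sequence across anchors. Minus-strand anchors are evaluated on the reverse
#' complement, so a positive value downstream of the TSS always means a G
#' excess on the template read by the elongating polymerase of the gene.
#'
#' @inheritParams gc_content_profile
#' @return A `meta_profile` tibble.
#' @export
gc_skew_profile <- function(genome, anchors, flank = 5000, bin = 100) {
  counts <- promoter_bin_base_counts(genome, anchors, flank, bin)
  # counts are plus-strand, already column-flipped for minus anchors;
  # on the reverse complement G and C swap roles
  g <- counts$G; c_ <- counts$C
  neg <- counts$anchor_strand == "-"
  skew <- (g - c_) / (g + c_)
  skew[neg, ] <- -skew[neg, , drop = FALSE]
  skew[(g + c_) == 0] <- NA_real_
  new_meta_profile(bin_positions(flank, bin),
                   colMeans(skew, na.rm = TRUE), nrow(skew))
}

# Per-anchor, per-bin base counts on the plus strand, orientation-flipped for
# minus-strand anchors (column 1 = most upstream). Anchors whose window
# exceeds the chromosome are dropped with a warning.
promoter_bin_base_counts <- function(genome, anchors, flank, bin) {
  if (!is(genome, "DNAStringSet")) abort("`genome` must be a DNAStringSet")
  if (flank %% bin != 0) abort("`flank` must be divisible by `bin`")
  anchors <- anchor_tbl(anchors)
  sl <- genome_seqlengths(genome)
  ws <- ifelse(anchors$strand == "+", anchors$tss - flank,
               anchors$tss - flank + 1L)
  ok <- anchors$chrom %in% names(sl) & ws >= 0 &
    (ws + 2L * flank) <= sl[anchors$chrom]
  if (any(!ok)) {
    warn(sprintf("dropping %d anchor(s) outside chromosome bounds", sum(!ok)))
    anchors <- anchors[ok, ]
    ws <- ws[ok]
  }
  if (nrow(anchors) == 0) abort("no usable anchors")
  n_bins <- as.integer(2L * flank / bin)
  n_anchor <- nrow(anchors)
  res <- list(A = matrix(0, n_anchor, n_bins), C = matrix(0, n_anchor, n_bins),
              G = matrix(0, n_anchor, n_bins), T = matrix(0, n_anchor, n_bins))
  for (ch in unique(anchors$chrom)) {
    idx <- which(anchors$chrom == ch)
    starts <- rep(ws[idx], each = n_bins) +
      rep((seq_len(n_bins) - 1L) * bin, times = length(idx))
    v <- Biostrings::Views(genome[[ch]],
                           IRanges::IRanges(starts + 1L, width = bin))
    f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    for (b in c("A", "C", "G", "T")) {
      res[[b]][idx, ] <- matrix(f[, b], ncol = n_bins, byrow = TRUE)
    }
  }
  neg <- anchors$strand == "-"
  for (b in c("A", "C", "G", "T")) {
    res[[b]][neg, ] <- res[[b]][neg, n_bins:1, drop = FALSE]
  }
  res$anchor_strand <- anchors$strand
  res$anchors <- anchors
  res
}

#' Detect CpG islands by sliding window
#'
#' Classical sliding-window caller: windows of `window` bp qualifying on both
#' GC fraction and observed/expected CpG ratio
#' (`obs/exp = N_CpG * L / (N_C * N_G)`) are merged; merged intervals shorter
#' than `min_len` are dropped, and each reported island is verified to
#' re-satisfy both thresholds (trimmed from the weaker end if needed). The
#' defaults are the classical island criteria (GC >= 0.5, obs/exp >= 0.6,
#' length >= 200 bp). For real genomes a curated island track (BED) should be
#' supplied instead via [read_bed_features()].
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param min_len Minimum island length (default 200).
#' @param min_gc Minimum GC fraction (default 0.5).
#' @param min_oe Minimum observed/expected CpG ratio (default 0.6).
#' @param window Sliding-window size in bp (default 200).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), `gc`,
#'   `obs_exp`, sorted and disjoint.
#' @export
detect_cpg_islands <- function(genome, min_len = 200, min_gc = 0.5,
                               min_oe = 0.6, window = 200) {
  if (!is(genome, "DNAStringSet")) abort("`genome` must be a DNAStringSet")
  out <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    L <- length(s)
    if (L < window) next
    f <- Biostrings::letterFrequencyInSlidingView(s, window, c("C", "G"))
    cg_pos <- Biostrings::start(Biostrings::matchPattern("CG", s))
    ncg_cum <- cumsum(tabulate(cg_pos, nbins = L))
    # CpG dinucleotides starting within window [i, i + window - 2]
    n_win <- L - window + 1L
    hi <- pmin(seq_len(n_win) + window - 2L, L)
    ncg <- ncg_cum[hi] - c(0, ncg_cum[seq_len(n_win - 1L)])
    gc_ok <- (f[, "C"] + f[, "G"]) >= min_gc * window
    oe <- ifelse(f[, "C"] * f[, "G"] == 0, 0,
                 ncg * window / (f[, "C"] * f[, "G"]))
    qual <- which(gc_ok & oe >= min_oe)
    if (length(qual) == 0) next
    isl <- IRanges::reduce(IRanges::IRanges(qual, qual + window - 1L))
    isl <- isl[IRanges::width(isl) >= min_len]
    for (k in seq_along(isl)) {
      iv <- refine_island(s, IRanges::start(isl)[k], IRanges::end(isl)[k],
                          min_len, min_gc, min_oe)
      if (!is.null(iv)) {
        out[[length(out) + 1L]] <- tibble(
          chrom = ch, start = iv$start - 1L, end = iv$end,
          gc = iv$gc, obs_exp = iv$oe
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gc = numeric(), obs_exp = numeric()))
  }
  arrange(bind_rows(out), .data$chrom, .data$start)
}

# shrink [start, end] (1-based closed) until both thresholds hold
refine_island <- function(s, start, end, min_len, min_gc, min_oe) {
  island_stats <- function(a, b) {
    sub <- Biostrings::subseq(s, a, b)
    f <- Biostrings::letterFrequency(sub, c("C", "G"))
    nc <- f[["C"]]; ng <- f[["G"]]
    ncg <- length(Biostrings::matchPattern("CG", sub))
    L <- b - a + 1
    list(gc = (nc + ng) / L,
         oe = if (nc * ng == 0) 0 else ncg * L / (nc * ng))
  }
  repeat {
    st <- island_stats(start, end)
    if (st$gc >= min_gc && st$oe >= min_oe) {
      return(list(start = start, end = end, gc = st$gc, oe = st$oe))
    }
    if (end - start + 1 - 10 < min_len) return(NULL)
    # trim 10 bp from the CG-poorer end
    head_f <- Biostrings::letterFrequency(
      Biostrings::subseq(s, start, start + 9), c("C", "G"))
    tail_f <- Biostrings::letterFrequency(
      Biostrings::subseq(s, end - 9, end), c("C", "G"))
    if (sum(head_f) <= sum(tail_f)) start <- start + 10L else end <- end - 10L
  }
}

#' Per-gene CpG island summary at promoters
#'
#' For every anchor: whether at least one island overlaps the core promoter
#' `[TSS - cover_window, TSS + cover_window)`, and the summed length of all
#' islands overlapping the wider `[TSS - size_window, TSS + size_window)`
#' region. Island lengths are summed in full by default even when an island
#' only partially overlaps the window (`clip = TRUE` clips to the window).
#'
#' @param islands Island tibble (`chrom`, `start`, `end`).
#' @param genes Transcript table or anchor tibble.
#' @param size_window Half-width of the size-summary window (default 1000,
#'   i.e. the 2 kb region around the TSS).
#' @param cover_window Half-width of the coverage window (default 500).
#' @param clip Clip island lengths to the size window before summing?
#' @return Tibble with `region_id`, `covered`, `total_island_bp`.
#' @export
promoter_cpg_summary <- function(islands, genes, size_window = 1000,
                                 cover_window = 500, clip = FALSE) {
  anchors <- anchor_tbl(genes)
  out <- tibble(region_id = anchors$region_id, covered = FALSE,
                total_island_bp = 0L)
  for (ch in unique(anchors$chrom)) {
    isl <- islands[islands$chrom == ch, ]
    idx <- which(anchors$chrom == ch)
    if (nrow(isl) == 0) next
    ir <- IRanges::IRanges(isl$start + 1L, isl$end)
    cover <- IRanges::IRanges(anchors$tss[idx] - cover_window + 1L,
                              anchors$tss[idx] + cover_window)
    size <- IRanges::IRanges(anchors$tss[idx] - size_window + 1L,
                             anchors$tss[idx] + size_window)
    out$covered[idx] <- IRanges::countOverlaps(cover, ir) > 0
    hits <- IRanges::findOverlaps(size, ir)
    if (length(hits) > 0) {
      w <- if (clip) {
        IRanges::width(IRanges::pintersect(
          size[S4Vectors::queryHits(hits)], ir[S4Vectors::subjectHits(hits)]))
      } else {
        IRanges::width(ir)[S4Vectors::subjectHits(hits)]
      }
      tot <- tapply(w, S4Vectors::queryHits(hits), sum)
      out$total_island_bp[idx[as.integer(names(tot))]] <- as.integer(tot)
    }
  }
  out
}

#' Cumulative 5' splice-site accumulation downstream of the TSS
#'
#' For each distance `x` from 1 to `span`, the fraction of genes with at
#' least one motif hit (log-odds score >= `threshold`) fully contained in the
#' first `x` nt downstream of the TSS on the sense strand. A hit starting at
#' (1-based) position `s` is counted from `x = s + motif_length - 1` onward,
#' so the curve is non-decreasing and bounded by 1.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param genes Transcript table or anchor tibble.
#' @param pwm A `pwm` object (see [read_jaspar()]).
#' @param span Number of nucleotides scanned downstream of the TSS.
#' @param threshold Score threshold in bits.
#' @return Tibble of class `accumulation_curve`: `x` (nt traversed),
#'   `fraction`.
#' @export
splice_site_accumulation <- function(genome, genes, pwm, span = 500,
                                     threshold) {
  anchors <- anchor_tbl(genes)
  W <- ncol(pwm$matrix)
  if (span <= W) abort("`span` must exceed the motif length")
  sl <- genome_seqlengths(genome)
  first_cover <- rep(NA_integer_, nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    seq_i <- sense_downstream_seq(genome, sl, anchors$chrom[i],
                                  anchors$tss[i], anchors$strand[i],
                                  span + W - 1L)
    if (nchar(seq_i) < W) next
    sc <- pwm_scan(seq_i, pwm)
    hit <- which(sc >= threshold)
    if (length(hit) > 0) first_cover[i] <- min(hit) + W - 1L
  }
  x <- seq_len(span)
  fraction <- vapply(x, function(xx) {
    mean(!is.na(first_cover) & first_cover <= xx)
  }, numeric(1))
  out <- tibble(x = x, fraction = fraction)
  class(out) <- c("accumulation_curve", class(out))
  out
}

# sense-strand sequence of `len` nt starting at the TSS, reading downstream;
# truncated at the chromosome edge
sense_downstream_seq <- function(genome, sl, chrom, tss, strand, len) {
  L <- sl[[chrom]]
  if (strand == "+") {
    a <- tss + 1L
    b <- min(tss + len, L)
    if (a > b) return("")
    as.character(Biostrings::subseq(genome[[chrom]], a, b))
  } else {
    a <- max(tss - len + 2L, 1L)
    b <- tss + 1L
    if (a > b) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(genome[[chrom]], a, b)))
  }
}
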