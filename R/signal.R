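#' Binned sense/antisense promoter signal
#'
#' Sums per-base coverage in fixed-width bins across the window
#' `[TSS - flank, TSS + flank)` of every anchor and splits the signal into a
#' sense channel (the anchor's own strand) and an antisense channel (the
#' opposite strand). Minus-strand anchors are orientation-flipped so that in
#' both output matrices column 1 is always the most-upstream bin and the TSS
#' base falls in the first downstream bin. Bin sums are transformed with
#' `log2(x + 1)` by default, matching how promoter heatmaps are usually
#' scaled; `transform = "raw"` keeps plain sums.
#'
#' Anchors whose window would run off the chromosome are dropped with a
#' warning rather than zero-padded.
#'
#' @param cov A `stranded_coverage` object.
#' @param anchors Transcript table or anchor tibble (see [anchor_tbl()]).
#' @param flank Half-window size in bp (default 5000).
#' @param bin Bin width in bp (default 100); must divide `flank`.
#' @param transform `"log2p1"` (default) or `"raw"`.
#' @return Object of class `binned_signal`: list with numeric matrices
#'   `sense` and `antisense` (rows = anchors, columns = bins, most-upstream
#'   first), the anchor tibble used, and the binning metadata.
#' @export
binned_promoter_signal <- function(cov, anchors, flank = 5000, bin = 100,
                                   transform = c("log2p1", "raw")) {
  transform <- match.arg(transform)
  if (flank %% bin != 0) abort("`flank` must be divisible by `bin`")
  anchors <- anchor_tbl(anchors)
  sl <- attr(cov, "seqlengths")
  ws <- ifelse(anchors$strand == "+", anchors$tss - flank,
               anchors$tss - flank + 1L)
  ok <- ws >= 0 & (ws + 2L * flank) <= sl[anchors$chrom] &
    anchors$chrom %in% names(sl)
  if (any(!ok)) {
    warn(sprintf("dropping %d anchor(s) whose %d bp window exceeds chromosome bounds",
                 sum(!ok), 2L * flank))
    anchors <- anchors[ok, ]
    ws <- ws[ok]
  }
  if (nrow(anchors) == 0) abort("no usable anchors")
  n_bins <- as.integer(2L * flank / bin)
  n_anchor <- nrow(anchors)

  bin_grid <- tibble(
    row = rep(seq_len(n_anchor), each = n_bins),
    j = rep(seq_len(n_bins), times = n_anchor)
  )
  bin_grid$start <- ws[bin_grid$row] + (bin_grid$j - 1L) * bin
  bin_grid$end <- bin_grid$start + bin
  bin_grid$chrom <- anchors$chrom[bin_grid$row]

  channel_matrix <- function(signal_strand_of) {
    bg <- bin_grid
    bg$strand <- signal_strand_of[bg$row]
    sums <- coverage_bin_sums(cov, bg)
    m <- matrix(sums, nrow = n_anchor, ncol = n_bins, byrow = TRUE)
    # flip minus-strand anchors so column 1 is most upstream
    neg <- anchors$strand == "-"
    m[neg, ] <- m[neg, n_bins:1, drop = FALSE]
    rownames(m) <- anchors$region_id
    if (transform == "log2p1") m <- log2(m + 1)
    m
  }

  sense <- channel_matrix(anchors$strand)
  antisense <- channel_matrix(opposite_strand(anchors$strand))
  structure(
    list(sense = sense, antisense = antisense, anchors = anchors,
         flank = flank, bin = bin, transform = transform),
    class = "binned_signal"
  )
}

#' @export
print.binned_signal <- function(x, ...) {
  cat(sprintf("<binned_signal> %d anchor(s) x %d bins (%d bp), flank %d, transform %s\n",
              nrow(x$sense), ncol(x$sense), x$bin, x$flank, x$transform))
  invisible(x)
}

#' Tidy a binned signal matrix into long form
#' @param x A `binned_signal`.
#' @param ... Unused.
#' @return Tibble with `region_id`, `channel`, `position` (bin-center offset
#'   from the TSS, bp) and `value`.
#' @export
tidy.binned_signal <- function(x, ...) {
  pos <- bin_positions(x$flank, x$bin)
  long <- function(m, channel) {
    tibble(
      region_id = rep(rownames(m), times = ncol(m)),
      channel = channel,
      position = rep(pos, each = nrow(m)),
      value = as.vector(m)
    )
  }
  bind_rows(long(x$sense, "sense"), long(x$antisense, "antisense"))
}

# bin-center positions relative to the TSS for a symmetric window
bin_positions <- function(flank, bin) {
  n_bins <- as.integer(2L * flank / bin)
  (seq_len(n_bins) - 1L) * bin - flank + bin / 2
}

#' Upstream antisense score per anchor
#'
#' Sums the most-upstream antisense bins per region — the statistic used to
#' rank promoters by divergent transcription and to calibrate the calling
#' threshold on intergenic regions.
#'
#' @param x A `binned_signal` (or a bare antisense matrix, upstream-first).
#' @param upstream_bins Number of leading (most-upstream) bins to sum;
#'   defaults to `flank / bin`, i.e. the full upstream half.
#' @return Tibble with `region_id` and `antisense_score` (for a matrix, a
#'   plain named numeric vector).
#' @export
antisense_score <- function(x, upstream_bins = NULL) {
  if (is.matrix(x)) {
    upstream_bins <- upstream_bins %||% (ncol(x) %/% 2)
    if (ncol(x) < upstream_bins) abort("fewer bins than `upstream_bins`")
    return(rowSums(x[, seq_len(upstream_bins), drop = FALSE]))
  }
  stopifnot(inherits(x, "binned_signal"))
  upstream_bins <- upstream_bins %||% as.integer(x$flank / x$bin)
  s <- antisense_score(x$antisense, upstream_bins)
  tibble(region_id = x$anchors$region_id, antisense_score = unname(s))
}

#' Metagene (average) profile around anchors
#'
#' Mean binned signal across anchors for one channel, oriented so negative
#' positions are upstream of the TSS in the direction of transcription.
#'
#' @inheritParams binned_promoter_signal
#' @param channel `"sense"` or `"antisense"`.
#' @return A `meta_profile` tibble: `position` (bp, bin centers), `mean`,
#'   `n_regions`.
#' @export
meta_profile <- function(cov, anchors, flank = 5000, bin = 100,
                         channel = c("sense", "antisense"),
                         transform = c("raw", "log2p1")) {
  channel <- match.arg(channel)
  transform <- match.arg(transform)
  bs <- binned_promoter_signal(cov, anchors, flank, bin, transform)
  m <- bs[[channel]]
  new_meta_profile(bin_positions(flank, bin), colMeans(m), nrow(m))
}

new_meta_profile <- function(position, mean, n_regions) {
  if (n_regions <= 0) abort("profile needs at least one region")
  out <- tibble(position = position, mean = as.numeric(mean),
                n_regions = n_regions)
  class(out) <- c("meta_profile", class(out))
  out
}

#' Average profile over length-rescaled regions
#'
#' Divides each region into `n_bins` equal-fraction bins (oriented 5' to 3'
#' along the region's strand), averages per-base coverage within each bin,
#' then averages across regions. Used for signals over regions of unequal
#' length, e.g. TSS to the end of the first intron.
#'
#' @param cov A `stranded_coverage`.
#' @param regions Tibble with `chrom`, `start`, `end`, `strand`.
#' @param n_bins Number of rescaled bins (default 100).
#' @param channel `"same"`, `"opposite"` or `"both"`: which strand's coverage
#'   to read relative to each region's strand.
#' @return A `meta_profile` tibble with `position` = bin index (1-based).
#' @export
rescaled_region_profile <- function(cov, regions, n_bins = 100,
                                    channel = c("same", "opposite", "both")) {
  channel <- match.arg(channel)
  regions <- as_tibble(regions)
  check_strand(regions$strand)
  len <- regions$end - regions$start
  ok <- len >= n_bins
  if (any(!ok)) {
    warn(sprintf("dropping %d region(s) shorter than %d bp", sum(!ok), n_bins))
    regions <- regions[ok, ]
    len <- len[ok]
  }
  if (nrow(regions) == 0) abort("no usable regions")
  acc <- matrix(0, nrow = nrow(regions), ncol = n_bins)
  for (i in seq_len(nrow(regions))) {
    strands <- switch(channel,
      same = regions$strand[i],
      opposite = opposite_strand(regions$strand[i]),
      both = c("+", "-")
    )
    v <- 0
    for (s in strands) {
      v <- v + coverage_window(cov, regions$chrom[i], s,
                               regions$start[i], regions$end[i])
    }
    bnd <- round(len[i] * seq(0, n_bins) / n_bins)
    means <- vapply(seq_len(n_bins), function(j) {
      mean(v[(bnd[j] + 1):bnd[j + 1]])
    }, numeric(1))
    if (regions$strand[i] == "-") means <- rev(means)
    acc[i, ] <- means
  }
  new_meta_profile(seq_len(n_bins), colMeans(acc), nrow(regions))
}

#' Fraction of anchors covered by a feature at each position
#'
#' At each strand-oriented offset from the TSS, the fraction of anchors whose
#' corresponding genomic base lies inside at least one feature interval
#' (e.g. conserved elements, CpG islands).
#'
#' @param features Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param anchors Transcript table or anchor tibble.
#' @param flank Half-window in bp.
#' @param step Offset step in bp (default 10).
#' @return A `meta_profile` tibble with values in \[0, 1\].
#' @export
feature_fraction_profile <- function(features, anchors, flank = 5000,
                                     step = 10) {
  anchors <- anchor_tbl(anchors)
  rel <- seq(-flank, flank, by = step)
  n_anchor <- nrow(anchors)
  if (n_anchor == 0) abort("no usable anchors")
  sign_dir <- ifelse(anchors$strand == "+", 1L, -1L)
  grid <- tibble(
    row = rep(seq_len(n_anchor), each = length(rel)),
    rel = rep(rel, times = n_anchor)
  )
  grid$pos <- anchors$tss[grid$row] + sign_dir[grid$row] * grid$rel
  grid$chrom <- anchors$chrom[grid$row]
  grid$hit <- FALSE
  for (ch in unique(grid$chrom)) {
    f <- features[features$chrom == ch, ]
    idx <- which(grid$chrom == ch)
    if (nrow(f) == 0) next
    fr <- IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
    pts <- IRanges::IRanges(grid$pos[idx] + 1L, grid$pos[idx] + 1L)
    grid$hit[idx] <- IRanges::countOverlaps(pts, fr) > 0
  }
  frac <- tapply(grid$hit, grid$rel, mean)
  new_meta_profile(rel, as.numeric(frac[as.character(rel)]), n_anchor)
}
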