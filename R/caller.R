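#' Sample random intergenic regions for null calibration
#'
#' Draws regions of fixed length uniformly from the parts of the genome lying
#' at least `buffer` bp away from any transcript span, and assigns each a
#' random pseudo-orientation so the antisense channel is defined exactly as
#' for genes. Each region also gets a pseudo-TSS placed so that the region is
#' its full upstream flank, which lets the identical binning/transform
#' pipeline score null regions and candidate promoters. Start positions are
#' constrained so the complete scoring window (`2 * length` bp) fits on the
#' chromosome; sampled regions may overlap one another.
#'
#' @param transcripts Transcript table whose spans (plus `buffer`) are masked.
#' @param genome Genome or named chromosome-length vector.
#' @param n Number of regions (default 10000).
#' @param length Region length in bp (default 5000).
#' @param buffer Minimum distance from any transcript span (default 1000).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return Tibble with `region_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
sample_intergenic_regions <- function(transcripts, genome, n = 10000,
                                      length = 5000, buffer = 1000, seed) {
  sl <- genome_seqlengths(genome)
  if (missing(seed)) abort("`seed` is required")
  pools <- list()
  for (ch in names(sl)) {
    L <- sl[[ch]]
    # eligible start s: [s, s + length) intergenic, full window within chrom
    lo <- length       # need s - length >= 0 for minus-strand windows
    hi <- L - 2L * length  # need s + 2*length <= L
    if (hi < lo) next
    free <- IRanges::IRanges(lo + 1L, hi + 1L)  # 1-based interval of s+1
    tx <- transcripts[transcripts$chrom == ch, ]
    if (nrow(tx) > 0) {
      mask <- IRanges::IRanges(pmax(tx$start - buffer - length + 1L, 0L) + 1L,
                               tx$end + buffer)
      free <- IRanges::setdiff(free, IRanges::reduce(mask))
    }
    if (sum(IRanges::width(free)) > 0) {
      pools[[ch]] <- tibble(chrom = ch,
                            lo = IRanges::start(free) - 1L,
                            n_start = IRanges::width(free))
    }
  }
  pool <- bind_rows(pools)
  if (nrow(pool) == 0) {
    abort(sprintf(
      "insufficient intergenic space for %d bp regions (0 eligible start positions)",
      length))
  }
  withr::with_seed(seed, {
    iv <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$n_start)
    off <- floor(runif(n) * pool$n_start[iv])
    s <- pool$lo[iv] + as.integer(off)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tibble(
      region_id = sprintf("null_%05d", seq_len(n)),
      chrom = pool$chrom[iv],
      start = s,
      end = s + as.integer(length),
      strand = strand,
      # pseudo-TSS such that the region is exactly the upstream flank
      tss = ifelse(strand == "+", s + as.integer(length), s - 1L)
    )
  })
}

#' Null distribution of antisense scores over intergenic regions
#'
#' Runs the same binning/transform/scoring path used for candidate promoters
#' on a set of intergenic regions and returns their upstream antisense
#' bin-sum scores.
#'
#' @param cov A `stranded_coverage`.
#' @param regions Output of [sample_intergenic_regions()].
#' @inheritParams binned_promoter_signal
#' @return Object of class `null_distribution`: tibble with `region_id` and
#'   `antisense_score`, carrying `flank`, `bin`, `transform` attributes.
#' @export
null_antisense_scores <- function(cov, regions, bin = 100,
                                  transform = c("log2p1", "raw")) {
  transform <- match.arg(transform)
  flank <- unique(regions$end - regions$start)
  if (length(flank) != 1) abort("null regions must share one length")
  bs <- binned_promoter_signal(cov, regions, flank = flank, bin = bin,
                               transform = transform)
  out <- antisense_score(bs)
  attr(out, "flank") <- flank
  attr(out, "bin") <- bin
  attr(out, "transform") <- transform
  class(out) <- c("null_distribution", class(out))
  out
}

#' Empirical calling threshold from a null score distribution
#'
#' The threshold is the k-th smallest null score with
#' `k = ceiling((1 - alpha) * M)`, which guarantees that the fraction of null
#' scores strictly above the threshold is at most `alpha` — the empirical
#' analogue of calling at p < `alpha` against the intergenic null.
#'
#' @param null_scores Numeric vector of null scores, or a tibble with an
#'   `antisense_score` column (e.g. from [null_antisense_scores()]).
#' @param alpha Tail probability (default 0.005).
#' @return The threshold score (numeric scalar).
#' @examples
#' empirical_threshold(1:1000, alpha = 0.005)  # 995
#' @export
empirical_threshold <- function(null_scores, alpha = 0.005) {
  if (is.data.frame(null_scores)) null_scores <- null_scores$antisense_score
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1")
  }
  m <- length(null_scores)
  if (m == 0) abort("empty null distribution")
  if (any(!is.finite(null_scores)) || any(null_scores < 0)) {
    abort("null scores must be finite and non-negative")
  }
  k <- ceiling((1 - alpha) * m)
  sort(null_scores)[k]
}

#' Call LUAT-positive promoters against a threshold
#'
#' A candidate is called when its upstream antisense score strictly exceeds
#' the threshold; ties at the threshold are not called, which preserves the
#' at-most-`alpha` null calibration exactly.
#'
#' @param scores Tibble with `region_id` (or `gene_id`) and
#'   `antisense_score`, one row per candidate.
#' @param threshold Threshold score from [empirical_threshold()].
#' @param candidates Optional transcript table; when given, every candidate
#'   must have a score (an error names any candidate without one) and
#'   `gene_id` is carried into the result.
#' @return Tibble of calls: `region_id`, `gene_id` (if known),
#'   `antisense_score`, `threshold`, `called`.
#' @export
call_luats <- function(scores, threshold, candidates = NULL) {
  scores <- as_tibble(scores)
  if (!"region_id" %in% names(scores) && "gene_id" %in% names(scores)) {
    scores$region_id <- scores$gene_id
  }
  if (!is.null(candidates)) {
    missing_sc <- setdiff(candidates$transcript_id, scores$region_id)
    if (length(missing_sc) > 0) {
      abort(paste0("no antisense score for candidate(s): ",
                   paste(head(missing_sc, 5), collapse = ", ")))
    }
    scores <- left_join(
      scores,
      tibble(region_id = candidates$transcript_id,
             gene_id = candidates$gene_id),
      by = "region_id"
    )
  }
  scores |>
    mutate(threshold = threshold,
           called = .data$antisense_score > threshold) |>
    select(dplyr::any_of(c("region_id", "gene_id")), "antisense_score",
           "threshold", "called")
}
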