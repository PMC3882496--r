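#' Per-base stranded coverage from aligned fragments
#'
#' Piles up stranded fragments into per-chromosome, per-strand run-length
#' encoded coverage vectors. Each fragment contributes 1 to every base it
#' overlaps; total coverage mass therefore equals the summed fragment lengths
#' per strand.
#'
#' @param reads Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand` ("+"/"-").
#' @param genome A [Biostrings::DNAStringSet] or named vector of chromosome
#'   lengths.
#' @return An object of class `stranded_coverage`: a list with elements
#'   `plus` and `minus`, each a named list of [S4Vectors::Rle] per-base
#'   coverage vectors, plus a `seqlengths` attribute.
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", start = 100L, end = 150L, strand = "+")
#' cov <- coverage_from_reads(reads, c(chr1 = 1000))
#' sum(cov$plus$chr1)  # 50
#' @export
coverage_from_reads <- function(reads, genome) {
  sl <- genome_seqlengths(genome)
  reads <- as_tibble(reads)
  check_strand(reads$strand)
  bad_chrom <- !reads$chrom %in% names(sl)
  if (any(bad_chrom)) {
    abort(sprintf("reads on unknown chromosome(s): %s",
                  paste(unique(reads$chrom[bad_chrom]), collapse = ", ")))
  }
  oob <- reads$start < 0 | reads$end > sl[reads$chrom] | reads$start >= reads$end
  if (any(oob)) {
    i <- which(oob)[1]
    abort(sprintf("out-of-bounds or empty fragment: %s:[%d,%d) %s",
                  reads$chrom[i], reads$start[i], reads$end[i], reads$strand[i]))
  }
  one_strand <- function(s) {
    d <- reads[reads$strand == s, ]
    out <- lapply(names(sl), function(ch) {
      di <- d[d$chrom == ch, ]
      IRanges::coverage(IRanges::IRanges(di$start + 1L, di$end),
                        width = sl[[ch]])
    })
    setNames(out, names(sl))
  }
  structure(
    list(plus = one_strand("+"), minus = one_strand("-")),
    seqlengths = sl,
    n_fragments = nrow(reads),
    class = "stranded_coverage"
  )
}

#' @export
print.stranded_coverage <- function(x, ...) {
  sl <- attr(x, "seqlengths")
  cat(sprintf("<stranded_coverage> %d chromosome(s), %d fragment(s)\n",
              length(sl), attr(x, "n_fragments") %||% NA_integer_))
  for (ch in names(sl)) {
    cat(sprintf("  %s (%d bp): + mass %.0f, - mass %.0f\n", ch, sl[[ch]],
                sum(x$plus[[ch]]), sum(x$minus[[ch]])))
  }
  invisible(x)
}

# strand name ("+"/"-") -> coverage slot name
strand_slot <- function(strand) ifelse(strand == "+", "plus", "minus")

# Sum coverage over arbitrary bins. `bins` is a tibble with columns chrom,
# strand ("+"/"-" = which coverage strand to read), start, end (0-based
# half-open). Returns a numeric vector aligned with the rows of `bins`.
coverage_bin_sums <- function(cov, bins) {
  out <- numeric(nrow(bins))
  key <- paste(bins$chrom, bins$strand)
  for (k in unique(key)) {
    idx <- which(key == k)
    ch <- bins$chrom[idx[1]]
    sl <- bins$strand[idx[1]]
    rle <- cov[[strand_slot(sl)]][[ch]]
    if (is.null(rle)) abort(sprintf("no coverage for chromosome '%s'", ch))
    v <- IRanges::Views(rle, IRanges::IRanges(bins$start[idx] + 1L,
                                              bins$end[idx]))
    out[idx] <- IRanges::viewSums(v)
  }
  out
}

# Extract a per-base numeric window [start, end) for one chrom/strand.
coverage_window <- function(cov, chrom, strand, start, end) {
  rle <- cov[[strand_slot(strand)]][[chrom]]
  if (is.null(rle)) abort(sprintf("no coverage for chromosome '%s'", chrom))
  as.numeric(S4Vectors::window(rle, start + 1L, end))
}
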