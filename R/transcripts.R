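#' Build a transcript table
#'
#' The central annotation container is an ordinary tibble with one row per
#' transcript and list-columns holding the exon structure. All coordinates are
#' 0-based half-open (BED convention); exons are stored in genomic order. The
#' constructor validates the structure and adds derived columns: the genomic
#' span (`start`, `end`), the strand-aware transcription start site `tss`
#' (for a minus-strand transcript this is `end - 1`, the 5'-most transcribed
#' base), the exon count and the summed exonic length.
#'
#' @param df A data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` ("+"/"-"), list-columns `exon_start` and `exon_end` (integer
#'   vectors, genomic order), and optionally `is_coding` (default `TRUE`).
#' @return A tibble of class `luat_transcripts` with derived columns
#'   `start`, `end`, `tss`, `n_exons`, `exonic_length`.
#' @examples
#' tx <- transcripts_tbl(tibble::tibble(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
#'   exon_start = list(c(100L, 500L)), exon_end = list(c(342L, 700L))
#' ))
#' tx$tss
#' @export
transcripts_tbl <- function(df) {
  df <- as_tibble(df)
  needed <- c("transcript_id", "gene_id", "chrom", "strand",
              "exon_start", "exon_end")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("missing transcript columns: ", paste(missing, collapse = ", ")))
  }
  if (!"is_coding" %in% names(df)) df$is_coding <- TRUE
  check_strand(df$strand)
  df$exon_start <- map(df$exon_start, as.integer)
  df$exon_end <- map(df$exon_end, as.integer)
  bad <- map2_lgl_safe(df$exon_start, df$exon_end)
  if (any(bad)) {
    abort(paste0("invalid exon structure for transcript(s): ",
                 paste(df$transcript_id[bad], collapse = ", ")))
  }
  df$start <- map_int(df$exon_start, ~ .x[1])
  df$end <- map_int(df$exon_end, ~ .x[length(.x)])
  df$n_exons <- map_int(df$exon_start, length)
  df$exonic_length <- map2_int(df$exon_start, df$exon_end, ~ sum(.y - .x))
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  class(df) <- c("luat_transcripts", class(df))
  df
}

# exons must be sorted, non-overlapping, non-empty, start < end
map2_lgl_safe <- function(starts, ends) {
  one_bad <- function(s, e) {
    if (length(s) == 0 || length(s) != length(e)) return(TRUE)
    if (any(e <= s)) return(TRUE)
    if (length(s) > 1 && any(s[-1] < e[-length(e)])) return(TRUE)
    FALSE
  }
  map2_lgl(starts, ends, one_bad)
}

#' Strand-aware first exon length
#'
#' The first exon is the 5'-most exon in the direction of transcription: the
#' leftmost exon for a plus-strand transcript, the rightmost for minus-strand.
#'
#' @param transcripts A transcript table (see [transcripts_tbl()]).
#' @return Integer vector of first-exon lengths (bp), one per transcript.
#' @examples
#' tx <- transcripts_tbl(tibble::tibble(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
#'   exon_start = list(c(100L, 500L)), exon_end = list(c(342L, 700L))
#' ))
#' first_exon_length(tx)  # 242
#' @export
first_exon_length <- function(transcripts) {
  pmap_int_fe <- function(s, e, strand) {
    if (strand == "+") e[1] - s[1] else e[length(e)] - s[length(s)]
  }
  as.integer(mapply(pmap_int_fe, transcripts$exon_start,
                    transcripts$exon_end, transcripts$strand))
}

#' Strand-aware first intron of a transcript
#'
#' @param transcripts A transcript table.
#' @return Tibble with `transcript_id`, `chrom`, `strand`, `start`, `end`
#'   of the first (5'-most) intron; transcripts without introns are dropped.
#' @export
first_intron <- function(transcripts) {
  tx <- dplyr::filter(transcripts, .data$n_exons >= 2)
  fi <- function(s, e, strand) {
    n <- length(s)
    if (strand == "+") c(e[1], s[2]) else c(e[n - 1], s[n])
  }
  ints <- mapply(fi, tx$exon_start, tx$exon_end, tx$strand)
  tibble(
    transcript_id = tx$transcript_id, chrom = tx$chrom, strand = tx$strand,
    start = as.integer(ints[1, ]), end = as.integer(ints[2, ])
  )
}

#' Introns of a transcript in strand (5' to 3') order
#' @param exon_start,exon_end Integer vectors of exon bounds (genomic order).
#' @param strand "+" or "-".
#' @return A two-column matrix (start, end) with one row per intron, ordered
#'   5' to 3' along the transcript; zero rows for single-exon transcripts.
#' @keywords internal
intron_bounds <- function(exon_start, exon_end, strand) {
  n <- length(exon_start)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  m <- cbind(exon_end[-n], exon_start[-1])
  if (strand == "-") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

# Genome helpers ---------------------------------------------------------

#' Chromosome lengths of a genome
#'
#' Accepts either a [Biostrings::DNAStringSet] or a named integer vector and
#' returns a named integer vector of chromosome lengths.
#' @param genome A `DNAStringSet` or named numeric vector of lengths.
#' @return Named integer vector.
#' @export
genome_seqlengths <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    sl <- setNames(Biostrings::width(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    sl <- setNames(as.integer(genome), names(genome))
  } else {
    abort("`genome` must be a DNAStringSet or a named vector of lengths")
  }
  if (anyDuplicated(names(sl))) abort("chromosome names must be unique")
  if (any(sl <= 0)) abort("chromosome lengths must be positive")
  sl
}

#' Anchor table from transcripts or a region tibble
#'
#' Normalizes an anchor set to the minimal columns (`region_id`, `chrom`,
#' `tss`, `strand`) used by the profiling and calling machinery. Transcripts
#' anchor at their TSS; plain region tibbles must already carry `tss`.
#' @param x Transcript table or tibble with `chrom`, `tss`, `strand` and an
#'   id column (`region_id` or `transcript_id`).
#' @return Tibble with columns `region_id`, `chrom`, `tss`, `strand`.
#' @export
anchor_tbl <- function(x) {
  x <- as_tibble(x)
  id <- if ("region_id" %in% names(x)) x$region_id else x$transcript_id
  if (is.null(id)) abort("anchors need a `region_id` or `transcript_id` column")
  if (!"tss" %in% names(x)) abort("anchors need a `tss` column")
  check_strand(x$strand)
  tibble(region_id = as.character(id), chrom = x$chrom,
         tss = as.integer(x$tss), strand = x$strand)
}
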