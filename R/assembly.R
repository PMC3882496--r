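#' Segment per-base coverage into transcribed fragments
#'
#' Finds maximal runs of per-base coverage at or above `min_cov` and keeps
#' those at least `min_len` bp long. This coverage-run segmentation supplies
#' the fragment input of the merge/extend assembler when no external
#' assembler output is available; externally produced fragment BED (e.g. from
#' a spliced assembler run on real alignments) can be used instead.
#'
#' @param cov A `stranded_coverage`.
#' @param chrom Chromosome name, or `NULL` for all chromosomes.
#' @param strand `"+"`, `"-"`, or `NULL` for both.
#' @param min_cov Minimum per-base coverage (default 1).
#' @param min_len Minimum fragment length in bp (default 200).
#' @return Tibble with `chrom`, `start`, `end`, `strand`, sorted and disjoint
#'   per chromosome/strand.
#' @export
segment_fragments <- function(cov, chrom = NULL, strand = NULL,
                              min_cov = 1, min_len = 200) {
  sl <- attr(cov, "seqlengths")
  chroms <- chrom %||% names(sl)
  strands <- strand %||% c("+", "-")
  out <- list()
  for (ch in chroms) {
    for (s in strands) {
      rle <- cov[[strand_slot(s)]][[ch]]
      if (is.null(rle)) abort(sprintf("no coverage for chromosome '%s'", ch))
      r <- IRanges::slice(rle, lower = min_cov, rangesOnly = TRUE)
      r <- r[IRanges::width(r) >= min_len]
      if (length(r) > 0) {
        out[[paste(ch, s)]] <- tibble(
          chrom = ch, start = IRanges::start(r) - 1L,
          end = IRanges::end(r), strand = s
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  arrange(bind_rows(out), .data$chrom, .data$strand, .data$start)
}

#' Merge and extend antisense fragments into a LUAT model
#'
#' Implements the seed/merge/extend assembly rule: fragments (on the strand
#' opposite the gene) whose strand-aware 5' end lies within `seed_window` bp
#' of the gene's TSS act as seeds; the model is then extended in both
#' directions, absorbing any fragment of length at least `min_len` whose gap
#' to the current span is strictly less than `max_gap`, until no further
#' fragment can be absorbed. The result is the union span of the absorbed
#' fragments. Because absorption uses a strict gap-below-`max_gap` rule, the
#' result equals the single-linkage gap-cluster that contains a seed; when
#' seeds fall in several clusters the one whose seed is closest to the TSS
#' wins.
#'
#' @param fragments Tibble with `start`, `end` (and optionally `chrom`,
#'   `strand`) holding antisense fragments; input order is irrelevant.
#' @param gene One-row transcript table (or list with `tss`, `strand`,
#'   `chrom`).
#' @param seed_window Seed distance from the TSS in bp (default 1500).
#' @param min_len Minimum fragment length in bp (default 200).
#' @param max_gap Strict upper bound on the gap between merged fragments
#'   (default 800; a gap of exactly 800 bp stops the extension).
#' @return One-row tibble (`chrom`, `start`, `end`, `strand`) or `NULL` when
#'   no seed fragment exists.
#' @examples
#' frags <- tibble::tibble(start = c(9500L, 8500L, 7000L),
#'                         end = c(9900L, 9100L, 8300L))
#' gene <- list(tss = 10000L, strand = "+", chrom = "chr1")
#' merge_extend_luat(frags, gene)  # [7000, 9900)
#' @export
merge_extend_luat <- function(fragments, gene, seed_window = 1500,
                              min_len = 200, max_gap = 800) {
  tss <- as.integer(gene$tss)
  gene_strand <- as.character(gene$strand)
  check_strand(gene_strand, "gene$strand")
  luat_strand <- opposite_strand(gene_strand)
  fr <- as_tibble(fragments)
  fr <- fr[(fr$end - fr$start) >= min_len, , drop = FALSE]
  if (nrow(fr) == 0) return(NULL)
  fr <- fr[order(fr$start, fr$end), , drop = FALSE]
  five <- if (luat_strand == "-") fr$end - 1L else fr$start
  is_seed <- abs(five - tss) <= seed_window
  if (!any(is_seed)) return(NULL)
  # single-linkage gap clusters: break where gap to running span >= max_gap
  run_end <- cummax(fr$end)
  new_cluster <- c(TRUE, fr$start[-1] - run_end[-nrow(fr)] >= max_gap)
  cl <- cumsum(new_cluster)
  seed_cl <- cl[is_seed]
  seed_dist <- abs(five - tss)[is_seed]
  chosen <- seed_cl[which.min(seed_dist)]
  members <- cl == chosen
  tibble(
    chrom = if ("chrom" %in% names(fr)) fr$chrom[members][1] else
      gene$chrom %||% NA_character_,
    start = min(fr$start[members]),
    end = max(fr$end[members]),
    strand = luat_strand
  )
}

#' Signed 5' offset of a LUAT relative to the gene TSS
#'
#' The distance from the LUAT's strand-aware 5' end to the TSS of its
#' associated gene, signed so that negative values mean the LUAT starts
#' upstream of the gene (in the gene's orientation).
#'
#' @param luat One-row tibble/list with `start`, `end` (the LUAT interval,
#'   on the strand opposite the gene).
#' @param gene One-row transcript table or list with `tss`, `strand`.
#' @return Signed integer offset in bp.
#' @export
luat_tss_offset <- function(luat, gene) {
  tss <- as.integer(gene$tss)
  if (gene$strand == "+") {
    as.integer(luat$end) - 1L - tss
  } else {
    tss - as.integer(luat$start)
  }
}

#' FPKM of a transcript model from stranded fragments
#'
#' A fragment is assigned to the model when it lies on the same strand and
#' overlaps the model's exons by at least one base. FPKM is
#' `1e9 * assigned / (exonic_length * library_size)`.
#'
#' @param reads Fragment tibble (`chrom`, `start`, `end`, `strand`).
#' @param model One-row tibble/list with `chrom`, `strand` and either
#'   `exon_start`/`exon_end` list-columns or plain `start`/`end` (treated as
#'   a single exon).
#' @param library_size Total mapped fragments in the library.
#' @return FPKM (numeric scalar).
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", start = seq(0, 49) * 40L,
#'                         end = seq(0, 49) * 40L + 50L, strand = "+")
#' model <- list(chrom = "chr1", strand = "+", start = 0L, end = 2000L)
#' quantify_fpkm(reads, model, library_size = 1e6)  # 25
#' @export
quantify_fpkm <- function(reads, model, library_size) {
  if (library_size <= 0) abort("`library_size` must be positive")
  has_exons <- all(c("exon_start", "exon_end") %in% names(model))
  es <- if (has_exons) unlist(model[["exon_start"]]) else model[["start"]]
  ee <- if (has_exons) unlist(model[["exon_end"]]) else model[["end"]]
  exonic_len <- sum(ee - es)
  if (exonic_len <= 0) abort("model has zero exonic length")
  d <- reads[reads$chrom == model$chrom & reads$strand == model$strand, ]
  if (nrow(d) == 0) return(0)
  hits <- IRanges::countOverlaps(
    IRanges::IRanges(d$start + 1L, d$end),
    IRanges::IRanges(es + 1L, ee)
  ) > 0
  1e9 * sum(hits) / (exonic_len * library_size)
}

#' Assemble and quantify LUATs for called promoters
#'
#' For every called candidate, takes the antisense coverage fragments on the
#' gene's chromosome, runs [merge_extend_luat()], and annotates the call with
#' the assembled interval, its signed 5' offset and its FPKM (quantified as a
#' single-exon span).
#'
#' @param calls Call tibble from [call_luats()] (rows with `called = TRUE`
#'   are assembled).
#' @param cov A `stranded_coverage` used for fragment segmentation.
#' @param candidates Transcript table holding the called transcripts
#'   (matched on `region_id` = `transcript_id`).
#' @param reads Fragment tibble for FPKM quantification.
#' @param library_size Total mapped fragments.
#' @param min_cov,min_len,seed_window,max_gap Assembly parameters (see
#'   [segment_fragments()] and [merge_extend_luat()]).
#' @return `calls` with added columns `luat_chrom`, `luat_start`, `luat_end`,
#'   `luat_strand`, `luat_offset`, `luat_fpkm` (NA when assembly found no
#'   seed).
#' @export
assemble_luats <- function(calls, cov, candidates, reads, library_size,
                           min_cov = 1, min_len = 200, seed_window = 1500,
                           max_gap = 800) {
  calls <- as_tibble(calls)
  calls$luat_chrom <- NA_character_
  calls$luat_start <- NA_integer_
  calls$luat_end <- NA_integer_
  calls$luat_strand <- NA_character_
  calls$luat_offset <- NA_integer_
  calls$luat_fpkm <- NA_real_
  todo <- which(calls$called)
  if (length(todo) == 0) return(calls)
  frag_cache <- list()
  cand_idx <- match(calls$region_id, candidates$transcript_id)
  for (i in todo) {
    g <- candidates[cand_idx[i], ]
    if (is.na(cand_idx[i])) {
      abort(sprintf("called region '%s' not found in candidates",
                    calls$region_id[i]))
    }
    ls <- opposite_strand(g$strand)
    key <- paste(g$chrom, ls)
    if (is.null(frag_cache[[key]])) {
      frag_cache[[key]] <- segment_fragments(cov, g$chrom, ls,
                                             min_cov = min_cov,
                                             min_len = min_len)
    }
    luat <- merge_extend_luat(frag_cache[[key]], g, seed_window = seed_window,
                              min_len = min_len, max_gap = max_gap)
    if (is.null(luat)) next
    calls$luat_chrom[i] <- luat$chrom
    calls$luat_start[i] <- luat$start
    calls$luat_end[i] <- luat$end
    calls$luat_strand[i] <- luat$strand
    calls$luat_offset[i] <- luat_tss_offset(luat, g)
    calls$luat_fpkm[i] <- quantify_fpkm(reads, luat, library_size)
  }
  calls
}
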