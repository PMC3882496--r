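#' Collapse isoforms with nearby TSSs to one representative
#'
#' Within each gene, transcripts whose TSSs lie strictly less than `window`
#' bp apart are clustered (single linkage along the TSS coordinate) and one
#' representative per cluster is kept: the longest transcript (genomic span),
#' ties broken by the lexicographically smallest `transcript_id`. The
#' operation is idempotent: surviving TSSs are pairwise at least `window` bp
#' apart.
#'
#' @param transcripts A transcript table.
#' @param window TSS clustering distance in bp (strict `<`, default 100).
#' @return The deduplicated transcript table.
#' @export
dedupe_tss <- function(transcripts, window = 100) {
  if (nrow(transcripts) == 0) return(transcripts)
  tx <- transcripts |>
    mutate(.span = .data$end - .data$start) |>
    arrange(.data$gene_id, .data$chrom, .data$tss)
  grp_key <- paste(tx$gene_id, tx$chrom)
  new_clust <- c(TRUE, diff(tx$tss) >= window | grp_key[-1] != grp_key[-nrow(tx)])
  tx$.clust <- cumsum(new_clust)
  out <- tx |>
    group_by(.data$.clust) |>
    arrange(dplyr::desc(.data$.span), .data$transcript_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".span", -".clust") |>
    arrange(.data$chrom, .data$start)
  class(out) <- class(transcripts)
  out
}

#' Select candidate promoters with a clear upstream region
#'
#' Keeps coding transcripts whose strand-aware upstream window
#' (`[TSS - upstream, TSS)` on the plus strand, the mirror on minus) does not
#' overlap the transcription unit (exon span) of any coding transcript from
#' another gene, on either strand. Transcripts whose upstream window (or the
#' symmetric downstream flank) would run off the chromosome are dropped so
#' that downstream binning always has a full window.
#'
#' @param transcripts Transcript table of candidates (coding rows are used).
#' @param genome Genome or named chromosome-length vector.
#' @param upstream Upstream window in bp (default 5000).
#' @param others Transcript table to screen against (defaults to
#'   `transcripts` itself); all coding transcripts of other genes count.
#' @return The filtered transcript table.
#' @export
select_candidate_promoters <- function(transcripts, genome, upstream = 5000,
                                       others = transcripts) {
  sl <- genome_seqlengths(genome)
  tx <- dplyr::filter(transcripts, .data$is_coding)
  unknown <- !tx$chrom %in% names(sl)
  if (any(unknown)) {
    abort(sprintf("transcript(s) on unknown chromosome: %s",
                  paste(head(tx$transcript_id[unknown], 5), collapse = ", ")))
  }
  up_start <- ifelse(tx$strand == "+", tx$tss - upstream, tx$tss + 1L)
  up_end <- up_start + upstream
  in_bounds <- tx$tss - upstream >= 0 & tx$tss + upstream < sl[tx$chrom]
  keep <- in_bounds
  ot <- dplyr::filter(others, .data$is_coding)
  for (ch in unique(tx$chrom)) {
    idx <- which(tx$chrom == ch & keep)
    if (length(idx) == 0) next
    o <- ot[ot$chrom == ch, ]
    if (nrow(o) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(up_start[idx] + 1L, up_end[idx]),
      IRanges::IRanges(o$start + 1L, o$end)
    )
    if (length(hits) > 0) {
      same_gene <- tx$gene_id[idx][S4Vectors::queryHits(hits)] ==
        o$gene_id[S4Vectors::subjectHits(hits)]
      bad <- unique(S4Vectors::queryHits(hits)[!same_gene])
      keep[idx[bad]] <- FALSE
    }
  }
  out <- tx[keep, ]
  class(out) <- class(transcripts)
  out
}

#' Partition genes into LUAT-associated, coding-coding and unidirectional sets
#'
#' Every gene receives exactly one label:
#' * `luat_associated` — called LUAT-positive and carrying a single
#'   (deduplicated) TSS; called genes with several alternative TSSs are
#'   excluded;
#' * `coding_coding` — an opposite-strand coding gene has a TSS strictly less
#'   than `head_to_head_sep` bp away (head-to-head pair sharing a
#'   bidirectional promoter);
#' * `unidirectional` — passed the clear-upstream candidate filter and was
#'   not called;
#' * `excluded` — everything else.
#'
#' @param candidates Candidate transcript table (from
#'   [select_candidate_promoters()]).
#' @param luat_calls Call tibble from [call_luats()].
#' @param all_transcripts Full transcript table (for alternative-TSS counts
#'   and head-to-head detection).
#' @param head_to_head_sep Maximum TSS separation for a head-to-head pair
#'   (strict `<`, default 1500).
#' @param dedupe_window TSS window used when counting alternative TSSs
#'   (default 100).
#' @return Tibble with `gene_id` and `label`.
#' @export
classify_gene_sets <- function(candidates, luat_calls, all_transcripts,
                               head_to_head_sep = 1500, dedupe_window = 100) {
  called_regions <- luat_calls$region_id[luat_calls$called] %||% character(0)
  if ("gene_id" %in% names(luat_calls)) {
    called_genes <- unique(luat_calls$gene_id[luat_calls$called])
  } else {
    called_genes <- unique(
      candidates$gene_id[candidates$transcript_id %in% called_regions])
  }
  unknown <- setdiff(called_genes, all_transcripts$gene_id)
  if (length(unknown) > 0) {
    abort(paste0("called gene(s) absent from annotation: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  rep_tx <- dedupe_tss(all_transcripts, window = dedupe_window)
  tss_count <- rep_tx |> count(.data$gene_id, name = "n_tss")
  # head-to-head: an opposite-strand coding gene's TSS strictly closer
  # than head_to_head_sep
  h2h_genes <- character(0)
  coding <- dplyr::filter(rep_tx, .data$is_coding)
  for (ch in unique(coding$chrom)) {
    d <- coding[coding$chrom == ch, ]
    if (nrow(d) < 2) next
    dd <- tidyr::expand_grid(i = seq_len(nrow(d)), j = seq_len(nrow(d))) |>
      dplyr::filter(.data$i < .data$j)
    pair_ok <- d$gene_id[dd$i] != d$gene_id[dd$j] &
      d$strand[dd$i] != d$strand[dd$j] &
      abs(d$tss[dd$i] - d$tss[dd$j]) < head_to_head_sep
    h2h_genes <- c(h2h_genes, d$gene_id[dd$i][pair_ok], d$gene_id[dd$j][pair_ok])
  }
  h2h_genes <- unique(h2h_genes)

  genes <- unique(all_transcripts$gene_id)
  single_tss <- tss_count$gene_id[tss_count$n_tss == 1]
  cand_genes <- unique(candidates$gene_id)
  label <- dplyr::case_when(
    genes %in% called_genes & genes %in% single_tss ~ "luat_associated",
    genes %in% called_genes ~ "excluded",     # several alternative TSSs
    genes %in% h2h_genes ~ "coding_coding",
    genes %in% cand_genes ~ "unidirectional",
    TRUE ~ "excluded"
  )
  tibble(gene_id = genes, label = label)
}

#' Sample expression-matched control genes
#'
#' Draws `n` control genes from `pool` so that the control set's expression
#' histogram over `n_bins` quantile bins of the reference distribution
#' matches the reference's. The per-bin control counts are allocated
#' proportionally to the reference's bin occupancy (largest-remainder
#' rounding), and genes are drawn without replacement within each bin.
#'
#' @param pool Character vector of candidate control gene ids (disjoint from
#'   the reference genes).
#' @param reference_expr Named numeric vector: expression per reference gene.
#' @param pool_expr Named numeric vector: expression per pool gene.
#' @param n Number of controls to draw (default: size of the reference set).
#' @param n_bins Number of quantile bins (default 10).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Character vector of `n` control gene ids, with attribute
#'   `ks_statistic`: the max |ECDF difference| between control and reference
#'   expression.
#' @export
sample_matched_controls <- function(pool, reference_expr, pool_expr,
                                    n = length(reference_expr), n_bins = 10,
                                    seed) {
  if (missing(seed)) abort("`seed` is required")
  if (length(intersect(pool, names(reference_expr))) > 0) {
    abort("`pool` must be disjoint from the reference genes")
  }
  pool_expr <- pool_expr[pool]
  if (anyNA(pool_expr)) abort("every pool gene needs a `pool_expr` value")
  if (n > length(pool)) abort("`n` exceeds the pool size")
  brk <- quantile(reference_expr, probs = seq(0, 1, length.out = n_bins + 1),
                  type = 7)
  brk <- unique(brk)
  if (length(brk) == 1) brk <- brk + c(-1e-8, 1e-8)
  nb <- length(brk) - 1
  ref_bin <- cut(reference_expr, brk, labels = FALSE, include.lowest = TRUE)
  # pool genes outside the reference range are ineligible as controls
  pool_bin <- cut(pool_expr, brk, labels = FALSE, include.lowest = TRUE)
  ref_n <- tabulate(ref_bin, nbins = nb)
  # largest-remainder allocation of n draws across bins
  raw <- n * ref_n / sum(ref_n)
  take <- floor(raw)
  rem <- n - sum(take)
  if (rem > 0) {
    ord <- order(raw - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  pool_n <- tabulate(pool_bin, nbins = nb)
  short <- which(take > pool_n)
  if (length(short) > 0) {
    abort(sprintf(
      "pool bin(s) %s hold too few genes (need %s, have %s); reduce `n_bins` or `n`",
      paste(short, collapse = ","), paste(take[short], collapse = ","),
      paste(pool_n[short], collapse = ",")))
  }
  controls <- withr::with_seed(seed, {
    unlist(lapply(seq_len(nb), function(b) {
      members <- pool[which(pool_bin == b)]
      if (take[b] == 0) return(character(0))
      members[sample.int(length(members), take[b])]
    }))
  })
  ks <- max_ecdf_gap(pool_expr[controls], reference_expr)
  attr(controls, "ks_statistic") <- ks
  controls
}

# max |ECDF_x - ECDF_y| over the pooled support
max_ecdf_gap <- function(x, y) {
  z <- sort(unique(c(x, y)))
  Fx <- vapply(z, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(z, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}
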