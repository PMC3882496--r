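#' Tissue-specificity score
#'
#' For each entity and condition, `TS = (e - Q3) / (Q3 - Q1)` where Q1 and Q3
#' are the first and third quartiles (type-7 linear interpolation) of the
#' entity's expression across all conditions. An entity is *specific* to a
#' condition when `TS > 1`, i.e. its expression there is an upper outlier of
#' its own distribution. A zero interquartile range leaves TS undefined
#' (`NA`) and the entity non-specific everywhere.
#'
#' @param expr Wide expression tibble: `entity_id` column plus one numeric
#'   column per condition (an optional `kind` column is carried through).
#' @return Tibble with `entity_id`, `condition`, `ts`, `specific`.
#' @examples
#' expr <- tibble::tibble(entity_id = "g1", t1 = 1, t2 = 2, t3 = 3,
#'                        t4 = 4, t5 = 100)
#' tissue_specificity(expr)  # ts for t5 is (100 - 4) / 2 = 48
#' @export
tissue_specificity <- function(expr) {
  expr <- as_tibble(expr)
  conds <- expr_conditions(expr)
  if (length(conds) < 4) abort("need at least 4 conditions for quartiles")
  m <- as.matrix(expr[, conds])
  q <- t(apply(m, 1, quantile, probs = c(0.25, 0.75), type = 7, names = FALSE))
  iqr <- q[, 2] - q[, 1]
  ts <- sweep(m, 1, q[, 2], "-") / iqr
  ts[iqr == 0, ] <- NA_real_
  tibble(
    entity_id = rep(expr$entity_id, times = length(conds)),
    condition = rep(conds, each = nrow(expr)),
    ts = as.vector(ts),
    specific = !is.na(as.vector(ts)) & as.vector(ts) > 1
  )
}

#' Pearson correlation of paired expression profiles
#'
#' Computes the Pearson correlation between the expression vectors of each
#' pair (e.g. a LUAT and its associated gene) across conditions. Pairs where
#' either member has zero variance are returned with `r = NA` and counted in
#' the `n_excluded` attribute.
#'
#' @param expr Wide expression tibble (see [tissue_specificity()]).
#' @param pairs Tibble with columns `id_a` and `id_b`.
#' @param log2 Correlate `log2(FPKM + pseudo)` instead of raw values?
#' @param pseudo Pseudo-count for the log transform (default 0.01).
#' @return Tibble with `id_a`, `id_b`, `r`; attribute `n_excluded`.
#' @export
pair_correlation <- function(expr, pairs, log2 = FALSE, pseudo = 0.01) {
  expr <- as_tibble(expr)
  conds <- expr_conditions(expr)
  m <- as.matrix(expr[, conds])
  rownames(m) <- expr$entity_id
  if (log2) m <- base::log2(m + pseudo)
  unknown <- setdiff(c(pairs$id_a, pairs$id_b), rownames(m))
  if (length(unknown) > 0) {
    abort(paste0("unknown entity id(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  a <- m[pairs$id_a, , drop = FALSE]
  b <- m[pairs$id_b, , drop = FALSE]
  va <- apply(a, 1, sd); vb <- apply(b, 1, sd)
  ok <- va > 0 & vb > 0
  r <- rep(NA_real_, nrow(pairs))
  r[ok] <- vapply(which(ok), function(i) cor(a[i, ], b[i, ]), numeric(1))
  out <- tibble(id_a = pairs$id_a, id_b = pairs$id_b, r = r)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Chi-square test of LUAT-gene co-regulation between two conditions
#'
#' Each pair member is classified as differentially expressed when
#' `|log2((x1 + pseudo) / (x2 + pseudo))| >= log2(fold)`. The 2x2
#' contingency table of (LUAT changed, gene changed) over all pairs is
#' tested with a chi-square statistic without continuity correction. A pair
#' counts as co-regulated only when both members changed in the same
#' direction. An error is raised when no pair has any differentially
#' expressed member (the table would be degenerate).
#'
#' @param expr_cond1,expr_cond2 Named numeric vectors of expression in the
#'   two conditions (names = entity ids; both LUATs and genes).
#' @param pairs Tibble with `id_a` (LUAT) and `id_b` (gene).
#' @param fold Fold-change threshold (default 2).
#' @param pseudo Pseudo-count (default 0.01).
#' @return Object of class `coregulation_test`: list with `table` (2x2),
#'   `statistic`, `p.value`, `n_pairs`, `n_used`, `pairs` (per-pair tibble
#'   with change flags, directions and `coregulated`).
#' @export
coregulation_test <- function(expr_cond1, expr_cond2, pairs, fold = 2,
                              pseudo = 0.01) {
  if (nrow(pairs) == 0) abort("no pairs supplied")
  need <- unique(c(pairs$id_a, pairs$id_b))
  missing_ids <- setdiff(need, intersect(names(expr_cond1), names(expr_cond2)))
  if (length(missing_ids) > 0) {
    abort(paste0("entity id(s) missing from an expression vector: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  lr <- function(ids) {
    base::log2((expr_cond1[ids] + pseudo) / (expr_cond2[ids] + pseudo))
  }
  ratio_a <- lr(pairs$id_a)
  ratio_b <- lr(pairs$id_b)
  thr <- base::log2(fold)
  chg_a <- abs(ratio_a) >= thr
  chg_b <- abs(ratio_b) >= thr
  per_pair <- tibble(
    id_a = pairs$id_a, id_b = pairs$id_b,
    log2fc_a = unname(ratio_a), log2fc_b = unname(ratio_b),
    changed_a = unname(chg_a), changed_b = unname(chg_b),
    coregulated = unname(chg_a & chg_b & sign(ratio_a) == sign(ratio_b))
  )
  used <- per_pair$changed_a | per_pair$changed_b
  if (!any(used)) abort("no pair has a differentially expressed member")
  tab <- table(
    factor(per_pair$changed_a, levels = c(TRUE, FALSE)),
    factor(per_pair$changed_b, levels = c(TRUE, FALSE)),
    dnn = c("luat_changed", "gene_changed")
  )
  res <- chi_square_2x2(unclass(tab))
  structure(
    list(table = tab, statistic = res$statistic, p.value = res$p.value,
         n_pairs = nrow(pairs), n_used = sum(used), fold = fold,
         pairs = per_pair),
    class = "coregulation_test"
  )
}

#' Closed-form Pearson chi-square on a 2x2 table
#'
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with no continuity correction,
#' compared against a chi-square distribution with one degree of freedom.
#'
#' @param m A 2x2 numeric matrix of counts.
#' @return List with `statistic` and `p.value`.
#' @examples
#' chi_square_2x2(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))$statistic  # 20
#' @export
chi_square_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- if (denom == 0) NA_real_ else n * (a * d - b * c_)^2 / denom
  list(statistic = stat,
       p.value = if (is.na(stat)) NA_real_ else pchisq(stat, df = 1,
                                                       lower.tail = FALSE))
}

#' @export
print.coregulation_test <- function(x, ...) {
  cat("Co-regulation chi-square test (no continuity correction)\n")
  print(x$table)
  cat(sprintf("X-squared = %.4g, df = 1, p = %.4g (%d of %d pairs used)\n",
              x$statistic, x$p.value, x$n_used, x$n_pairs))
  invisible(x)
}

#' @export
tidy.coregulation_test <- function(x, ...) x$pairs

#' @export
glance.coregulation_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, df = 1,
         n_pairs = x$n_pairs, n_used = x$n_used,
         n_coregulated = sum(x$pairs$coregulated))
}

#' Splicing index from per-feature FPKM values
#'
#' Quantifies immature (unspliced) transcription as log2 ratios of exonic to
#' intronic signal. Only transcripts with at least `min_exons` exons and
#' transcript FPKM above `min_fpkm` are scored. The 5' index compares the
#' mean FPKM of exons 1-2 with intron 1; the middle index compares the
#' central exon (mean of the two central exons when the exon count is even)
#' with the mean of its flanking introns. All features are pseudo-counted
#' before the ratio. Features are numbered 5' to 3' along the transcript.
#'
#' @param features Tibble with `transcript_id`, `feature` ("exon"/"intron"),
#'   `index` (1-based, 5' to 3'), `fpkm`.
#' @param transcript_fpkm Named numeric vector of whole-transcript FPKMs.
#' @param pseudo Pseudo-count added to each feature FPKM (default 0.01).
#' @param min_exons Minimum exon count (default 4).
#' @param min_fpkm Minimum transcript FPKM, exclusive (default 0.1).
#' @param middle_introns `"both"` (mean of the introns flanking the central
#'   exon(s), default) or `"upstream"` (the 5' flanking intron only).
#' @return Tibble with `transcript_id`, `si_5prime`, `si_middle` and the
#'   component FPKMs; skipped transcripts are reported in the `skipped`
#'   attribute.
#' @export
splicing_index <- function(features, transcript_fpkm, pseudo = 0.01,
                           min_exons = 4, min_fpkm = 0.1,
                           middle_introns = c("both", "upstream")) {
  middle_introns <- match.arg(middle_introns)
  features <- as_tibble(features)
  ids <- unique(features$transcript_id)
  skipped <- character(0)
  rows <- list()
  for (id in ids) {
    f <- features[features$transcript_id == id, ]
    ex <- f[f$feature == "exon", ]
    it <- f[f$feature == "intron", ]
    ex <- ex[order(ex$index), ]
    it <- it[order(it$index), ]
    n <- nrow(ex)
    tfpkm <- unname(transcript_fpkm[id])
    if (is.na(tfpkm) || n < min_exons || tfpkm <= min_fpkm) {
      skipped <- c(skipped, id)
      next
    }
    e <- ex$fpkm + pseudo
    i <- it$fpkm + pseudo
    si5 <- base::log2(mean(e[1:2]) / i[1])
    if (n %% 2 == 1) {
      k <- (n + 1) / 2
      mid_e <- e[k]
      flank <- c(i[k - 1], i[k])
    } else {
      k <- n / 2
      mid_e <- mean(e[c(k, k + 1)])
      flank <- c(i[k - 1], i[k + 1])
    }
    mid_i <- if (middle_introns == "both") mean(flank) else flank[1]
    rows[[id]] <- tibble(
      transcript_id = id, si_5prime = si5,
      si_middle = base::log2(mid_e / mid_i),
      exonic_5prime = mean(e[1:2]), intron1 = i[1],
      exonic_middle = mid_e, intron_middle = mid_i
    )
  }
  out <- if (length(rows) == 0) {
    tibble(transcript_id = character(), si_5prime = numeric(),
           si_middle = numeric(), exonic_5prime = numeric(),
           intron1 = numeric(), exonic_middle = numeric(),
           intron_middle = numeric())
  } else bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Per-feature FPKM table for a transcript's exons and introns
#'
#' Counts same-strand fragments overlapping each exon and intron (numbered 5'
#' to 3') and converts counts to FPKM. Feeds [splicing_index()].
#'
#' @param reads Fragment tibble (`chrom`, `start`, `end`, `strand`).
#' @param transcripts Transcript table.
#' @param library_size Total mapped fragments.
#' @return Tibble with `transcript_id`, `feature`, `index`, `start`, `end`,
#'   `fpkm`.
#' @export
feature_fpkm <- function(reads, transcripts, library_size) {
  if (library_size <= 0) abort("`library_size` must be positive")
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    es <- tx$exon_start[[1]]; ee <- tx$exon_end[[1]]
    ord <- if (tx$strand == "+") seq_along(es) else rev(seq_along(es))
    exon_tbl <- tibble(feature = "exon", index = seq_along(es),
                       start = es[ord], end = ee[ord])
    ib <- intron_bounds(es, ee, tx$strand)
    intron_tbl <- if (nrow(ib) > 0) {
      tibble(feature = "intron", index = seq_len(nrow(ib)),
             start = ib[, 1], end = ib[, 2])
    } else NULL
    feats <- bind_rows(exon_tbl, intron_tbl)
    d <- reads[reads$chrom == tx$chrom & reads$strand == tx$strand, ]
    counts <- if (nrow(d) == 0) rep(0L, nrow(feats)) else {
      IRanges::countOverlaps(
        IRanges::IRanges(feats$start + 1L, feats$end),
        IRanges::IRanges(d$start + 1L, d$end)
      )
    }
    feats$fpkm <- 1e9 * counts / ((feats$end - feats$start) * library_size)
    feats$transcript_id <- tx$transcript_id
    rows[[i]] <- feats
  }
  bind_rows(rows) |> select("transcript_id", dplyr::everything())
}

#' Read density in the first intron
#'
#' Number of same-strand fragments overlapping the strand-aware first intron,
#' divided by the intron length — reads per bp of immature transcription at
#' the 5' end of the gene.
#'
#' @param reads Fragment tibble.
#' @param transcripts Transcript table (intron-less transcripts raise an
#'   error).
#' @return Tibble with `transcript_id`, `n_reads`, `intron_length`,
#'   `density` (reads per bp).
#' @export
first_intron_density <- function(reads, transcripts) {
  no_intron <- transcripts$n_exons < 2
  if (any(no_intron)) {
    abort(paste0("transcript(s) without introns: ",
                 paste(head(transcripts$transcript_id[no_intron], 5),
                       collapse = ", ")))
  }
  fi <- first_intron(transcripts)
  n <- map_dbl(seq_len(nrow(fi)), function(i) {
    d <- reads[reads$chrom == fi$chrom[i] & reads$strand == fi$strand[i], ]
    if (nrow(d) == 0) return(0)
    sum(d$start < fi$end[i] & d$end > fi$start[i])
  })
  tibble(
    transcript_id = fi$transcript_id,
    n_reads = as.integer(n),
    intron_length = fi$end - fi$start,
    density = n / (fi$end - fi$start)
  )
}
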