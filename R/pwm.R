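#' Position weight matrices
#'
#' A `pwm` is a list with `motif_id`, a 4 x L numeric `matrix` of log2-odds
#' scores (rows A, C, G, T; bits against the background), and the `background`
#' probabilities. Count matrices are converted with a pseudo-count and a flat
#' background by default; `N` (or any non-ACGT base) scores as the column
#' minimum, so ambiguous sequence can never create a hit.
#'
#' @param counts 4 x L numeric matrix of base counts (rows A, C, G, T).
#' @param motif_id Motif identifier.
#' @param pseudo Pseudo-count added per cell (default 0.01).
#' @param background Background base probabilities (must sum to 1).
#' @return An object of class `pwm`.
#' @export
pwm_from_counts <- function(counts, motif_id = "motif", pseudo = 0.01,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("count matrix must have 4 rows (A, C, G, T)")
  if (abs(sum(background) - 1) > 1e-8) abort("background must sum to 1")
  rownames(counts) <- c("A", "C", "G", "T")
  p <- sweep(counts + pseudo, 2, colSums(counts + pseudo), "/")
  m <- log2(p / background)
  structure(list(motif_id = motif_id, matrix = m, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, length %d\n", x$motif_id, ncol(x$matrix)))
  print(round(x$matrix, 2))
  invisible(x)
}

#' Read a JASPAR-format PWM text file
#'
#' Parses the JASPAR flat format: a `>ID name` header followed by four lines
#' `A [ n n ... ]` etc. (brackets optional). Counts are converted to log2-odds
#' via [pwm_from_counts()].
#'
#' @param path Path to a JASPAR-format text file.
#' @inheritParams pwm_from_counts
#' @return A `pwm` object.
#' @export
read_jaspar <- function(path, pseudo = 0.01, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grep("^>", lines)
  if (length(header) == 0) {
    motif_id <- "motif"
    body <- lines
  } else {
    motif_id <- sub("^>\\s*", "", lines[header[1]])
    motif_id <- strsplit(motif_id, "\\s+")[[1]][1]
    body <- lines[(header[1] + 1):min(header[1] + 4, length(lines))]
  }
  rows <- lapply(body[1:4], function(l) {
    l <- sub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("\\[|\\]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  counts <- do.call(rbind, rows)
  pwm_from_counts(counts, motif_id = motif_id, pseudo = pseudo,
                  background = background)
}

# score every start position of `seq` (character scalar) against the pwm;
# non-ACGT bases score the column minimum
pwm_scan <- function(seq, pwm) {
  m <- pwm$matrix
  W <- ncol(m)
  code <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  n <- length(code)
  if (n < W) return(numeric(0))
  ext <- rbind(m, apply(m, 2, min))   # 5th row: score for N
  ns <- n - W + 1L
  sc <- numeric(ns)
  for (j in seq_len(W)) {
    sc <- sc + ext[cbind(code[j:(j + ns - 1L)], j)]
  }
  sc
}

#' Maximum PWM score in a promoter window
#'
#' Scans the sense-strand sequence of `[TSS - window/2, TSS + window/2)` for
#' each gene and returns the maximum log2-odds score. Windows reaching past a
#' chromosome edge are truncated with a warning; an all-ambiguous window
#' returns `-Inf`.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param genes Transcript table or anchor tibble.
#' @param pwm A `pwm` object.
#' @param window Window width in bp centered on the TSS (default 500).
#' @return Tibble with `region_id` and `max_score` (bits).
#' @export
pwm_max_score <- function(genome, genes, pwm, window = 500) {
  anchors <- anchor_tbl(genes)
  W <- ncol(pwm$matrix)
  if (window < W) abort("`window` must be at least the motif length")
  sl <- genome_seqlengths(genome)
  half <- window %/% 2
  truncated <- FALSE
  score <- vapply(seq_len(nrow(anchors)), function(i) {
    tss <- anchors$tss[i]
    L <- sl[[anchors$chrom[i]]]
    if (anchors$strand[i] == "+") {
      a <- tss - half; b <- tss + half - 1L
    } else {
      a <- tss - half + 1L; b <- tss + half
    }
    if (a < 0 || b >= L) {
      truncated <<- TRUE
      a <- max(a, 0L); b <- min(b, L - 1L)
    }
    s <- as.character(Biostrings::subseq(genome[[anchors$chrom[i]]],
                                         a + 1L, b + 1L))
    if (anchors$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    sc <- pwm_scan(s, pwm)
    if (length(sc) == 0) -Inf else max(sc)
  }, numeric(1))
  if (truncated) warn("some windows were truncated at chromosome edges")
  tibble(region_id = anchors$region_id, max_score = score)
}

#' Score of a PWM's consensus sequence
#'
#' Sum over columns of the per-column maximum — the highest score the motif
#' can achieve, useful for setting scan thresholds relative to the optimum.
#'
#' @param pwm A `pwm` object.
#' @return Numeric scalar (bits).
#' @export
pwm_consensus_score <- function(pwm) sum(apply(pwm$matrix, 2, max))

#' Consensus sequence of a PWM
#' @param pwm A `pwm` object.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste0(rownames(pwm$matrix)[apply(pwm$matrix, 2, which.max)], collapse = "")
}
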