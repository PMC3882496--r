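#' Read transcript annotation from GTF
#'
#' Parses a GTF with `gene_id`/`transcript_id` attributes via
#' [rtracklayer::import()] and assembles exon records into a transcript table.
#' GTF 1-based closed coordinates are converted to the internal 0-based
#' half-open convention on read.
#'
#' @param path Path to a GTF file.
#' @param coding_types `transcript_biotype`/`gene_biotype` values treated as
#'   coding when present; transcripts without a biotype attribute are assumed
#'   coding.
#' @return A transcript table (see [transcripts_tbl()]).
#' @export
read_gtf <- function(path, coding_types = "protein_coding") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  md <- as.data.frame(gr)
  biotype <- md$transcript_biotype %||% md$gene_biotype
  exons <- tibble(
    transcript_id = md$transcript_id,
    gene_id = md$gene_id,
    chrom = as.character(md$seqnames),
    strand = as.character(md$strand),
    start = md$start - 1L,   # to 0-based half-open
    end = md$end,
    is_coding = if (is.null(biotype)) TRUE else
      (is.na(biotype) | biotype %in% coding_types)
  )
  exons <- dplyr::arrange(exons, .data$transcript_id, .data$start)
  tx <- exons |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id), chrom = first(.data$chrom),
      strand = first(.data$strand), is_coding = first(.data$is_coding),
      exon_start = list(.data$start), exon_end = list(.data$end),
      .groups = "drop"
    )
  transcripts_tbl(tx)
}

#' Write a transcript table to GTF
#'
#' Emits one `transcript` and per-exon `exon` records per row, converting the
#' internal 0-based half-open coordinates back to GTF's 1-based closed form.
#'
#' @param transcripts A transcript table.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path, source = "luatscan") {
  rows <- pmap(
    list(transcripts$transcript_id, transcripts$gene_id, transcripts$chrom,
         transcripts$strand, transcripts$exon_start, transcripts$exon_end),
    function(tid, gid, chrom, strand, es, ee) {
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      tx_line <- c(chrom, source, "transcript", es[1] + 1L, ee[length(ee)],
                   ".", strand, ".", attr_str)
      ex_lines <- mapply(function(s, e) {
        c(chrom, source, "exon", s + 1L, e, ".", strand, ".", attr_str)
      }, es, ee, SIMPLIFY = FALSE)
      do.call(rbind, c(list(tx_line), ex_lines))
    }
  )
  m <- do.call(rbind, rows)
  readr::write_tsv(as.data.frame(m), path, col_names = FALSE, escape = "none")
  invisible(path)
}

#' Read stranded fragments from BED6
#'
#' @param path Path to a BED6 file (0-based half-open, strand in column 6).
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
read_bed_reads <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write stranded fragments to BED6
#'
#' @param reads Tibble with `chrom`, `start`, `end`, `strand`.
#' @param path Output path.
#' @param name Optional name column values (default ".").
#' @return `path`, invisibly.
#' @export
write_bed_reads <- function(reads, path, name = NULL) {
  nm <- name %||% rep(".", nrow(reads))
  df <- data.frame(reads$chrom, reads$start, reads$end, nm, 0L, reads$strand)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a feature interval track from BED
#'
#' @param path Path to a BED3+ file.
#' @param label Track label stored as the `label` attribute.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), sorted.
#' @export
read_bed_features <- function(path, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) |> arrange(.data$chrom, .data$start)
  attr(out, "label") <- label
  out
}

#' Write per-strand coverage to bedGraph
#'
#' One file per strand, runs of constant coverage as bedGraph intervals.
#' @param cov A stranded coverage object (see [coverage_from_reads()]).
#' @param prefix Output path prefix; files `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` are written.
#' @return Character vector of the two paths, invisibly.
#' @export
write_bedgraph <- function(cov, prefix) {
  paths <- character(2)
  for (i in seq_along(c("plus", "minus"))) {
    strand <- c("plus", "minus")[i]
    paths[i] <- paste0(prefix, ".", strand, ".bedgraph")
    rows <- imap(cov[[strand]], function(rle, chrom) {
      v <- S4Vectors::runValue(rle)
      l <- S4Vectors::runLength(rle)
      e <- cumsum(l)
      s <- e - l
      keep <- which(v != 0)
      data.frame(chrom = rep(chrom, length(keep)), start = s[keep],
                 end = e[keep], value = v[keep])
    })
    readr::write_tsv(dplyr::bind_rows(rows), paths[i], col_names = FALSE)
  }
  invisible(paths)
}

#' Read and write expression tables
#'
#' Expression tables are wide tibbles: an `entity_id` column, an optional
#' `kind` column ("gene" or "luat"), and one numeric column per condition
#' holding FPKM values.
#'
#' @param path TSV path.
#' @return A tibble (for the reader) or `path` invisibly (for the writer).
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_expression
#' @param expr Expression tibble.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

# condition (numeric) columns of an expression table
expr_conditions <- function(expr) {
  setdiff(names(expr)[vapply(expr, is.numeric, logical(1))], "entity_id")
}

#' Write a genome to FASTA
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] with uppercase sequence.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
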