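#' Full LUAT detection pipeline on one read set
#'
#' Runs the complete screen: TSS deduplication, clear-upstream candidate
#' selection, stranded coverage, binned promoter signal, upstream antisense
#' scores, an empirical null from random intergenic regions (scored through
#' the identical binning/transform path), threshold derivation, calling, and
#' (optionally) merge/extend assembly with FPKM quantification of the
#' resulting LUAT models.
#'
#' @param reads Fragment tibble (`chrom`, `start`, `end`, `strand`).
#' @param transcripts Transcript table (coding annotation).
#' @param genome Genome ([Biostrings::DNAStringSet]) or named length vector.
#' @param seed Integer seed (drives intergenic-region sampling).
#' @param flank,bin,transform Binning parameters (see
#'   [binned_promoter_signal()]).
#' @param alpha Null tail probability for the threshold (default 0.005).
#' @param null_n Number of intergenic calibration regions (default 10000).
#' @param null_buffer Distance kept from transcript spans (default 1000).
#' @param dedupe_window TSS deduplication window (default 100).
#' @param library_size Library size for FPKM (default: number of fragments).
#' @param assemble Assemble and quantify LUAT models for called genes?
#' @param min_cov,min_len,seed_window,max_gap Assembly parameters.
#' @return Object of class `luat_scan`: list with `candidates`, `calls`,
#'   `threshold`, `null_scores`, `signal` (the candidate `binned_signal`),
#'   and the parameters used.
#' @export
scan_luats <- function(reads, transcripts, genome, seed,
                       flank = 5000, bin = 100,
                       transform = c("log2p1", "raw"),
                       alpha = 0.005, null_n = 10000, null_buffer = 1000,
                       dedupe_window = 100, library_size = NULL,
                       assemble = TRUE, min_cov = 1, min_len = 200,
                       seed_window = 1500, max_gap = 800) {
  transform <- match.arg(transform)
  if (missing(seed)) abort("`seed` is required")
  library_size <- library_size %||% attr(reads, "library_size") %||% nrow(reads)
  deduped <- dedupe_tss(transcripts, window = dedupe_window)
  candidates <- select_candidate_promoters(deduped, genome,
                                           upstream = flank,
                                           others = transcripts)
  cov <- coverage_from_reads(reads, genome)
  signal <- binned_promoter_signal(cov, candidates, flank = flank, bin = bin,
                                   transform = transform)
  scores <- antisense_score(signal)
  null_regions <- sample_intergenic_regions(transcripts, genome, n = null_n,
                                            length = flank,
                                            buffer = null_buffer, seed = seed)
  null_scores <- null_antisense_scores(cov, null_regions, bin = bin,
                                       transform = transform)
  threshold <- empirical_threshold(null_scores, alpha = alpha)
  calls <- call_luats(scores, threshold, candidates = candidates)
  if (assemble) {
    calls <- assemble_luats(calls, cov, candidates, reads, library_size,
                            min_cov = min_cov, min_len = min_len,
                            seed_window = seed_window, max_gap = max_gap)
  }
  structure(
    list(candidates = candidates, calls = calls, threshold = threshold,
         null_scores = null_scores, null_regions = null_regions,
         signal = signal, coverage = cov,
         params = list(flank = flank, bin = bin, transform = transform,
                       alpha = alpha, null_n = null_n, seed = seed,
                       library_size = library_size)),
    class = "luat_scan"
  )
}

#' @export
print.luat_scan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<luat_scan> %d candidates, %d called (%.2f%%), threshold %.3f (alpha %.3g, %d null regions)\n",
    g$n_candidates, g$n_called, 100 * g$called_fraction, x$threshold,
    x$params$alpha, x$params$null_n))
  invisible(x)
}

#' @export
tidy.luat_scan <- function(x, ...) x$calls

#' @export
glance.luat_scan <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$calls),
    n_called = sum(x$calls$called),
    called_fraction = mean(x$calls$called),
    n_assembled = sum(!is.na(x$calls$luat_start %||% NA)),
    threshold = x$threshold,
    alpha = x$params$alpha,
    null_n = x$params$null_n
  )
}

#' Run the simulate-detect-characterize pipeline end to end
#'
#' Simulates a genome, annotation, stranded read set and multi-tissue
#' expression panel from one configuration, writes every stage product to
#' `outdir` (FASTA, GTF, BED, TSV tables), runs the LUAT screen, classifies
#' gene sets, summarizes promoter features and expression statistics, and
#' writes a machine-readable `summary.json` plus a `manifest.yaml` recording
#' inputs, parameters, seed and package version.
#'
#' @param config A [sim_config()] (or a YAML path understood by
#'   [yaml::read_yaml()] holding its arguments).
#' @param outdir Output directory (created if needed).
#' @param alpha,null_n Calling parameters passed to [scan_luats()].
#' @return The summary list, invisibly.
#' @export
run_end_to_end <- function(config, outdir, alpha = 0.005, null_n = 10000) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    config <- do.call(sim_config, args)
  }
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  ann <- simulate_annotation(sim, config)
  reads <- simulate_reads(ann, config = config)
  mt <- simulate_multitissue(config)

  write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_gtf(ann$transcripts, file.path(outdir, "annotation.gtf"))
  write_bed_reads(reads, file.path(outdir, "reads.bed"))
  readr::write_tsv(ann$truth, file.path(outdir, "truth.tsv"))
  write_expression(mt$expr, file.path(outdir, "expression.tsv"))

  scan <- scan_luats(reads, ann$transcripts, sim$genome, seed = config$seed,
                     alpha = alpha, null_n = null_n,
                     library_size = config$expression$library_size)
  readr::write_tsv(scan$calls, file.path(outdir, "calls.tsv"))
  sets <- classify_gene_sets(scan$candidates, scan$calls, ann$transcripts)
  readr::write_tsv(sets, file.path(outdir, "gene_sets.tsv"))

  offsets <- scan$calls$luat_offset
  offsets <- offsets[!is.na(offsets)]
  brk <- seq(-1500, 0, by = 250)
  offset_hist <- if (length(offsets) > 0) {
    h <- hist(pmax(pmin(offsets, 0), -1500), breaks = brk, plot = FALSE)
    setNames(as.list(h$counts), paste0("[", head(brk, -1), ",", brk[-1], ")"))
  } else list()

  fe <- tibble(gene_id = ann$transcripts$gene_id,
               first_exon = first_exon_length(ann$transcripts)) |>
    left_join(sets, by = "gene_id") |>
    group_by(.data$label) |>
    summarise(median_first_exon = median(.data$first_exon), .groups = "drop")

  feats <- feature_fpkm(reads, dplyr::filter(ann$transcripts, .data$n_exons >= 4),
                        config$expression$library_size)
  tx_fpkm <- setNames(
    map_dbl(seq_len(nrow(ann$transcripts)), function(i) {
      quantify_fpkm(reads, ann$transcripts[i, ],
                    config$expression$library_size)
    }), ann$transcripts$transcript_id)
  si <- splicing_index(feats, tx_fpkm)

  ts <- tissue_specificity(mt$expr)
  pc <- pair_correlation(mt$expr, mt$pairs, log2 = TRUE)

  summary <- list(
    package = "luatscan",
    version = as.character(utils::packageVersion("luatscan")),
    seed = config$seed,
    n_candidates = nrow(scan$calls),
    n_called = sum(scan$calls$called),
    called_fraction = mean(scan$calls$called),
    threshold = scan$threshold,
    offset_histogram = offset_hist,
    median_first_exon_by_set = setNames(as.list(fe$median_first_exon),
                                        fe$label),
    splicing_index = list(mean_si_5prime = mean(si$si_5prime),
                          mean_si_middle = mean(si$si_middle),
                          n_transcripts = nrow(si)),
    tissue_specificity = list(
      n_specific_calls = sum(ts$specific),
      mean_pair_correlation = mean(pc$r, na.rm = TRUE)
    )
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "luatscan",
    version = as.character(utils::packageVersion("luatscan")),
    seed = config$seed,
    config = unclass(config),
    parameters = list(alpha = alpha, null_n = null_n),
    outputs = c("genome.fa", "annotation.gtf", "reads.bed", "truth.tsv",
                "expression.tsv", "calls.tsv", "gene_sets.tsv",
                "summary.json")
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(summary)
}
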