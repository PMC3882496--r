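#' Simulation configuration
#'
#' Builds the configuration object that drives the synthetic genome,
#' annotation, read-set and multi-tissue generators. Defaults describe a
#' desk-scale divergent-transcription study: a 2 x 25 Mb genome (large enough
#' that planted antisense transcripts stay a negligible fraction of
#' intergenic space, as they are in a mammalian genome), 200 coding genes of
#' which 25% carry a planted long upstream antisense transcript (LUAT) and
#' 10% sit in head-to-head pairs with TSSs closer than 1.5 kb, first-exon
#' length medians of 242/190/195 bp for the LUAT-associated, head-to-head
#' and unidirectional classes, LUAT lengths log-normal around 2 kb with 5'
#' offsets concentrated within 500 bp upstream of the TSS, gene and LUAT
#' FPKM medians of 3.9 and 0.8, and a 17-condition expression panel.
#'
#' @param seed Integer seed; mandatory, drives every generator
#'   deterministically.
#' @param genome,genes,expression,tissues Named lists overriding individual
#'   defaults (recursively merged).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, genome = list(), genes = list(),
                       expression = list(), tissues = list()) {
  defaults <- list(
    seed = as.integer(seed),
    genome = list(
      n_chrom = 2L,
      chrom_length = 25e6,
      gc = 0.42,
      margin = 20000,
      skew = list(
        span = 500,
        downstream = c(luat_associated = 0.3, coding_coding = 0.3,
                       unidirectional = 0.3),
        upstream = c(luat_associated = -0.3, coding_coding = -0.3,
                     unidirectional = 0)
      ),
      cpg = list(
        prob = c(luat_associated = 0.8, coding_coding = 0.89,
                 unidirectional = 0.56),
        length_median = c(luat_associated = 1200, coding_coding = 700,
                          unidirectional = 400),
        length_sdlog = 0.25,
        cg_rate = 0.3,   # probability of emitting a CpG dinucleotide
        gc = 0.6         # GC of non-CpG island positions
      )
    ),
    genes = list(
      n = 200L,
      luat_fraction = 0.25,
      head_to_head_fraction = 0.10,
      n_exons = 4:8,
      exon_length = list(meanlog = log(170), sdlog = 0.3),
      first_exon_median = c(luat_associated = 242, coding_coding = 190,
                            unidirectional = 195),
      first_exon_sdlog = 0.25,
      intron_length = list(meanlog = log(800), sdlog = 0.5),
      head_to_head_sep = c(300, 1400),
      min_gap = 15000,
      mean_extra_gap = 60000
    ),
    expression = list(
      gene_fpkm = list(meanlog = log(3.9), sdlog = 1.0),
      luat_fpkm = list(meanlog = log(0.8), sdlog = 0.8, min = 0),
      luat_length = list(meanlog = log(2000), sdlog = 0.45,
                         min = 500, max = 4500),
      luat_offset_sd = 250,
      retention = c(luat_associated = 0, coding_coding = 0,
                    unidirectional = 0),
      background_per_kb = 0.2,
      library_size = 1.5e7,
      fragment_length = 100L
    ),
    tissues = list(
      n = 17L,
      rho = 0.7,
      specific_fraction = 0.3,
      boost = 10,
      gene_log = list(meanlog = log(3.9), sdlog = 0.7),
      luat_log = list(meanlog = log(0.8), sdlog = 0.7)
    )
  )
  cfg <- defaults
  cfg$genome <- merge_list(cfg$genome, genome)
  cfg$genes <- merge_list(cfg$genes, genes)
  cfg$expression <- merge_list(cfg$expression, expression)
  cfg$tissues <- merge_list(cfg$tissues, tissues)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

merge_list <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_list(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_sim_config <- function(cfg) {
  if (is.null(cfg$seed) || is.na(cfg$seed)) abort("`seed` is mandatory")
  fr <- c(cfg$genes$luat_fraction, cfg$genes$head_to_head_fraction,
          cfg$genome$cpg$prob, cfg$expression$retention,
          cfg$tissues$specific_fraction)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (abs(cfg$tissues$rho) > 1) abort("|rho| must not exceed 1")
  if (cfg$expression$library_size <= 0) abort("library_size must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d: %d x %.3g bp genome, %d genes (%.0f%% LUAT, %.0f%% head-to-head), %d tissues\n",
              x$seed, x$genome$n_chrom, x$genome$chrom_length, x$genes$n,
              100 * x$genes$luat_fraction,
              100 * x$genes$head_to_head_fraction, x$tissues$n))
  invisible(x)
}

# Deterministic structural layout shared by the genome and annotation
# generators: gene classes, placements, exon structures, LUAT truth and
# per-entity expression parameters. Uses its own RNG stream.
sim_layout <- function(config) {
  cfg <- config
  withr::with_seed(cfg$seed, sim_layout_impl(cfg))
}

sim_layout_impl <- function(cfg) {
  g <- cfg$genes
  n <- g$n
  empty_truth <- tibble(
    entity_id = character(), kind = character(), gene_id = character(),
    class = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), tss = integer(), fpkm = numeric(),
    retention = numeric(), luat_offset = integer(), luat_length = integer()
  )
  if (n == 0) {
    return(list(transcripts = transcripts_tbl(tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), exon_start = list(), exon_end = list()
    )), truth = empty_truth))
  }
  n_pairs <- round(n * g$head_to_head_fraction / 2)
  n_luat <- round(n * g$luat_fraction)
  n_uni <- n - 2 * n_pairs - n_luat
  if (n_uni < 0) abort("class fractions exceed the gene count")
  # units: single genes (luat or unidirectional) or head-to-head pairs
  unit_class <- sample(c(rep("luat_associated", n_luat),
                         rep("unidirectional", n_uni),
                         rep("pair", n_pairs)))
  chrom_names <- sprintf("chr%d", seq_len(cfg$genome$n_chrom))
  L <- cfg$genome$chrom_length
  margin <- cfg$genome$margin
  cur_chrom <- 1L
  cur <- margin
  gene_rows <- list()
  truth_rows <- list()
  gi <- 0L
  make_gene <- function(class) {
    k <- sample(g$n_exons, 1)
    fe <- round(rlnorm(1, log(g$first_exon_median[[class]]),
                       g$first_exon_sdlog))
    ex <- c(fe, round(rlnorm(k - 1, g$exon_length$meanlog,
                             g$exon_length$sdlog)))
    it <- round(rlnorm(k - 1, g$intron_length$meanlog, g$intron_length$sdlog))
    ex <- pmax(ex, 30); it <- pmax(it, 60)
    list(exons = ex, introns = it, span = sum(ex) + sum(it))
  }
  # genomic exon bounds for a gene starting (5' end) at `tss`
  gene_coords <- function(tss, strand, struct) {
    ex <- struct$exons; it <- struct$introns
    lens <- c(rbind(ex, c(it, 0)))[seq_len(2 * length(ex) - 1)]
    if (strand == "+") {
      edges <- tss + c(0, cumsum(lens))
    } else {
      edges <- rev(tss + 1 - c(0, cumsum(lens)))
    }
    starts <- edges[-length(edges)]
    ends <- edges[-1]
    is_exon <- if (strand == "+") seq_along(lens) %% 2 == 1 else
      rev(seq_along(lens) %% 2 == 1)
    list(exon_start = as.integer(starts[is_exon]),
         exon_end = as.integer(ends[is_exon]))
  }
  place <- function(width) {
    gap <- g$min_gap + stats::rexp(1, 1 / g$mean_extra_gap)
    pos <- cur + gap
    while (pos + width > L - margin) {
      cur_chrom <<- cur_chrom + 1L
      if (cur_chrom > cfg$genome$n_chrom) {
        abort(sprintf(
          "genome too small for the requested genes (placed %d of %d); enlarge chromosomes or reduce `n`",
          gi, n))
      }
      cur <<- margin
      pos <- cur + g$min_gap + stats::rexp(1, 1 / g$mean_extra_gap)
    }
    prev_end <- cur
    cur <<- pos + width
    list(start = round(pos), chrom = chrom_names[cur_chrom],
         prev_end = round(prev_end))
  }
  e <- cfg$expression
  add_gene <- function(chrom, tss, strand, class, struct, prev_end) {
    gi <<- gi + 1L
    id <- sprintf("gene%03d", gi)
    co <- gene_coords(tss, strand, struct)
    gene_rows[[gi]] <<- tibble(
      transcript_id = paste0(id, ".1"), gene_id = id, chrom = chrom,
      strand = strand, exon_start = list(co$exon_start),
      exon_end = list(co$exon_end), is_coding = TRUE
    )
    fpkm <- rlnorm(1, e$gene_fpkm$meanlog, e$gene_fpkm$sdlog)
    truth_rows[[length(truth_rows) + 1L]] <<- tibble(
      entity_id = paste0(id, ".1"), kind = "gene", gene_id = id,
      class = class, chrom = chrom, strand = strand,
      start = min(co$exon_start), end = max(co$exon_end),
      tss = tss, fpkm = fpkm,
      retention = unname(e$retention[[class]] %||% 0),
      luat_offset = NA_integer_, luat_length = NA_integer_
    )
    if (class == "luat_associated") {
      len <- round(min(max(rlnorm(1, e$luat_length$meanlog,
                                  e$luat_length$sdlog),
                           e$luat_length$min), e$luat_length$max))
      off <- -round(abs(rnorm(1, 0, e$luat_offset_sd)))
      off <- max(off, -1400L)
      if (strand == "+") {
        five <- tss + off
        lstart <- max(five - len + 1L, prev_end + 200L)
        luat <- c(lstart, five + 1L)
      } else {
        five <- tss - off
        luat <- c(five, five + len)
      }
      lf <- max(rlnorm(1, e$luat_fpkm$meanlog, e$luat_fpkm$sdlog),
                e$luat_fpkm$min)
      truth_rows[[length(truth_rows) + 1L]] <<- tibble(
        entity_id = paste0(id, ".luat"), kind = "luat", gene_id = id,
        class = class, chrom = chrom, strand = opposite_strand(strand),
        start = as.integer(luat[1]), end = as.integer(luat[2]),
        tss = NA_integer_, fpkm = lf, retention = 0,
        luat_offset = as.integer(off),
        luat_length = as.integer(luat[2] - luat[1])
      )
    }
  }
  for (u in unit_class) {
    if (u == "pair") {
      s1 <- make_gene("coding_coding")
      s2 <- make_gene("coding_coding")
      sep <- round(runif(1, g$head_to_head_sep[1], g$head_to_head_sep[2]))
      width <- s1$span + sep + s2$span
      at <- place(width)
      tss_minus <- at$start + s1$span - 1L
      add_gene(at$chrom, tss_minus, "-", "coding_coding", s1, at$prev_end)
      add_gene(at$chrom, tss_minus + sep, "+", "coding_coding", s2,
               at$prev_end)
    } else {
      s1 <- make_gene(u)
      at <- place(s1$span)
      strand <- sample(c("+", "-"), 1)
      tss <- if (strand == "+") at$start else at$start + s1$span - 1L
      add_gene(at$chrom, tss, strand, u, s1, at$prev_end)
    }
  }
  list(
    transcripts = transcripts_tbl(bind_rows(gene_rows)),
    truth = bind_rows(truth_rows)
  )
}

#' Simulate a genome with planted promoter sequence features
#'
#' Generates i.i.d. background sequence at the configured GC, then plants at
#' every simulated promoter (deterministically shared with
#' [simulate_annotation()]): a CpG-dense island centered on the TSS (with
#' class-specific probability and length), and a strand-oriented GC-skew
#' block — a G excess of the configured amplitude downstream of the TSS and
#' the configured (typically mirrored) amplitude upstream, in the gene's
#' reading orientation.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a [Biostrings::DNAStringSet]), `cpg_islands`
#'   (tibble of planted islands) and `skew_regions` (tibble with the planted
#'   sense-orientation amplitude per region).
#' @export
simulate_genome <- function(config) {
  lay <- sim_layout(config)
  gcfg <- config$genome
  chrom_names <- sprintf("chr%d", seq_len(gcfg$n_chrom))
  genes <- lay$truth[lay$truth$kind == "gene", ]
  withr::with_seed(config$seed + 1L, {
    plants <- plan_promoter_plants(genes, gcfg)
    seqs <- lapply(chrom_names, function(ch) {
      s <- random_dna_raw(gcfg$chrom_length, gcfg$gc)
      p <- plants[plants$chrom == ch, ]
      for (k in seq_len(nrow(p))) {
        if (p$end[k] > gcfg$chrom_length || p$start[k] < 0) {
          abort("planted feature exceeds chromosome bounds")
        }
        s[(p$start[k] + 1L):p$end[k]] <- charToRaw(p$seq[k])
      }
      rawToChar(s)
    })
  })
  genome <- Biostrings::DNAStringSet(setNames(unlist(seqs), chrom_names))
  list(
    genome = genome,
    cpg_islands = plants[plants$type == "cpg",
                         c("chrom", "start", "end", "gene_id")],
    skew_regions = plants[plants$type == "skew",
                          c("chrom", "start", "end", "gene_id", "amplitude",
                            "side")]
  )
}

# random DNA as a character scalar, GC fraction `gc`, optional skew
# (skew = (G - C) / (G + C) on the plus strand)
random_dna <- function(n, gc, skew = 0) {
  if (n == 0) return("")
  rawToChar(random_dna_raw(n, gc, skew))
}

random_dna_raw <- function(n, gc, skew = 0) {
  p <- c((1 - gc) / 2, gc * (1 - skew) / 2, gc * (1 + skew) / 2, (1 - gc) / 2)
  idx <- sample.int(4L, n, replace = TRUE, prob = p)
  as.raw(c(65L, 67L, 71L, 84L))[idx]  # A C G T
}

# CpG-island-like DNA: emit a CG dinucleotide with probability cg_rate,
# otherwise one base at the island GC level
random_cpg_dna <- function(n, cg_rate, gc) {
  out <- character(0)
  len <- 0
  while (len < n) {
    k <- ceiling((n - len) / (1 + cg_rate))  # expected tokens needed
    is_cg <- runif(k) < cg_rate
    tok <- ifelse(is_cg, "CG", strsplit(random_dna(k, gc), "")[[1]])
    out <- c(out, tok)
    len <- len + sum(ifelse(is_cg, 2, 1))
  }
  substr(paste0(out, collapse = ""), 1, n)
}

plan_promoter_plants <- function(genes, gcfg) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cls <- g$class
    # CpG island centered on the TSS, class-specific probability and size
    if (runif(1) < gcfg$cpg$prob[[cls]]) {
      len <- round(rlnorm(1, log(gcfg$cpg$length_median[[cls]]),
                          gcfg$cpg$length_sdlog))
      s <- g$tss - len %/% 2
      rows[[length(rows) + 1L]] <- tibble(
        chrom = g$chrom, start = as.integer(s), end = as.integer(s + len),
        gene_id = g$gene_id, type = "cpg", amplitude = NA_real_,
        side = NA_character_,
        seq = random_cpg_dna(len, gcfg$cpg$cg_rate, gcfg$cpg$gc)
      )
    }
    # GC skew blocks flanking the TSS, amplitudes in gene orientation
    span <- gcfg$skew$span
    for (side in c("downstream", "upstream")) {
      amp <- gcfg$skew[[side]][[cls]]
      if (amp == 0) next
      if (g$strand == "+") {
        iv <- if (side == "downstream") c(g$tss, g$tss + span) else
          c(g$tss - span, g$tss)
        plus_amp <- amp
      } else {
        iv <- if (side == "downstream") c(g$tss - span + 1L, g$tss + 1L) else
          c(g$tss + 1L, g$tss + span + 1L)
        plus_amp <- -amp
      }
      rows[[length(rows) + 1L]] <- tibble(
        chrom = g$chrom, start = as.integer(iv[1]), end = as.integer(iv[2]),
        gene_id = g$gene_id, type = "skew", amplitude = amp, side = side,
        seq = random_dna(span, gcfg$gc, plus_amp)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gene_id = character(), type = character(),
                  amplitude = numeric(), side = character(),
                  seq = character()))
  }
  bind_rows(rows)
}

#' Simulate a transcript annotation with planted ground truth
#'
#' Places non-overlapping genes with clear (>= 5 kb) upstream regions except
#' for the designated head-to-head pairs (opposite strands, TSS separation
#' below 1.5 kb), draws class-specific first-exon lengths, and attaches the
#' planted LUAT intervals, offsets and expression levels as a truth table.
#'
#' @param genome Output of [simulate_genome()] (or a genome/length vector)
#'   used to validate bounds.
#' @param config A [sim_config()].
#' @return List with `transcripts` (transcript table) and `truth` (tibble
#'   with one row per simulated entity: genes and LUATs, their class, planted
#'   interval, FPKM, first-intron retention rate and LUAT offset).
#' @export
simulate_annotation <- function(genome, config) {
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  sl <- genome_seqlengths(genome)
  lay <- sim_layout(config)
  if (nrow(lay$truth) > 0) {
    bad <- lay$truth$end > sl[lay$truth$chrom] | lay$truth$start < 0
    if (any(bad)) abort("simulated annotation exceeds genome bounds")
  }
  lay
}

#' Simulate a stranded fragment set
#'
#' Forward model of a total RNA-seq library: per transcript, the fragment
#' count is Poisson with mean `FPKM * exonic_kb * library_Mfrags`; fragments
#' fall uniformly on the mature transcript (within exons), except that a
#' per-transcript fraction of fragments derives from intron-1-retaining
#' pre-mRNA and falls uniformly across the 5' region spanning exon 1 through
#' exon 2. Planted LUATs produce antisense fragments over their interval.
#' Background fragments land uniformly genome-wide on both strands at the
#' configured per-kb rate. Fragments have fixed length (truncated at feature
#' boundaries), carry the strand of their source, and the `origin` column
#' records the generating entity.
#'
#' @param annotation Output of [simulate_annotation()] (uses `transcripts`).
#' @param truth Truth table (defaults to the annotation's).
#' @param config A [sim_config()].
#' @param seed Seed for the read draw (default `config$seed + 2`).
#' @return Tibble of fragments: `chrom`, `start`, `end`, `strand`, `origin`,
#'   plus attributes `library_size` and `fragment_length`.
#' @export
simulate_reads <- function(annotation, truth = annotation$truth, config,
                           seed = config$seed + 2L) {
  e <- config$expression
  if (e$library_size <= 0) abort("library_size must be positive")
  tx <- annotation$transcripts
  fl <- e$fragment_length
  lib_m <- e$library_size / 1e6
  sl <- setNames(rep(config$genome$chrom_length, config$genome$n_chrom),
                 sprintf("chr%d", seq_len(config$genome$n_chrom)))
  withr::with_seed(seed, {
    frags <- list()
    gene_truth <- truth[truth$kind == "gene", , drop = FALSE]
    for (i in seq_len(nrow(gene_truth))) {
      tr <- gene_truth[i, ]
      j <- match(tr$entity_id, tx$transcript_id)
      es <- tx$exon_start[[j]]; ee <- tx$exon_end[[j]]
      mu <- tr$fpkm * (sum(ee - es) / 1000) * lib_m
      n <- rpois(1, mu)
      if (n == 0) next
      n_imm <- rbinom(1, n, tr$retention)
      pos <- sample_exon_positions(es, ee, n - n_imm, fl)
      if (n_imm > 0) {
        # 5' pre-mRNA region: exon 1 through exon 2, strand-aware
        k <- length(es)
        span <- if (tr$strand == "+") c(es[1], ee[min(2, k)]) else
          c(es[max(k - 1, 1)], ee[k])
        s <- floor(runif(n_imm, span[1], max(span[2] - fl, span[1] + 1)))
        pos <- rbind(pos, cbind(s, pmin(s + fl, span[2])))
      }
      frags[[length(frags) + 1L]] <- tibble(
        chrom = tr$chrom, start = as.integer(pos[, 1]),
        end = as.integer(pos[, 2]), strand = tr$strand, origin = tr$entity_id
      )
    }
    luat_truth <- truth[truth$kind == "luat", , drop = FALSE]
    for (i in seq_len(nrow(luat_truth))) {
      tr <- luat_truth[i, ]
      mu <- tr$fpkm * ((tr$end - tr$start) / 1000) * lib_m
      n <- rpois(1, mu)
      if (n == 0) next
      pos <- sample_exon_positions(tr$start, tr$end, n, fl)
      frags[[length(frags) + 1L]] <- tibble(
        chrom = tr$chrom, start = as.integer(pos[, 1]),
        end = as.integer(pos[, 2]), strand = tr$strand, origin = tr$entity_id
      )
    }
    for (ch in names(sl)) {
      for (s in c("+", "-")) {
        nb <- rpois(1, e$background_per_kb * sl[[ch]] / 1000)
        if (nb == 0) next
        st <- floor(runif(nb, 0, sl[[ch]] - fl))
        frags[[length(frags) + 1L]] <- tibble(
          chrom = ch, start = as.integer(st), end = as.integer(st + fl),
          strand = s, origin = "background"
        )
      }
    }
  })
  out <- if (length(frags) == 0) {
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), origin = character())
  } else bind_rows(frags)
  out <- arrange(out, .data$chrom, .data$start)
  attr(out, "library_size") <- e$library_size
  attr(out, "fragment_length") <- fl
  out
}

# n fragment intervals uniform over the mature transcript: exon chosen
# proportional to length, start uniform within, truncated at the exon end
sample_exon_positions <- function(es, ee, n, fl) {
  if (n == 0) return(matrix(integer(0), ncol = 2))
  w <- ee - es
  j <- sample.int(length(es), n, replace = TRUE, prob = w)
  avail <- pmax(w[j] - fl, 1)
  s <- es[j] + floor(runif(n) * avail)
  cbind(s, pmin(s + fl, ee[j]))
}

#' Simulate a multi-tissue expression table with paired LUATs
#'
#' Gene log-expression is normal per tissue; a configured fraction of genes
#' is tissue-specific (one random tissue boosted by the configured factor).
#' Each LUAT-class gene gets a paired LUAT whose log-expression is generated
#' with the configured correlation `rho` to its gene (shared standardized
#' deviations plus independent noise), so co-expression recovery can be
#' tested against a known planted value.
#'
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed + 3`).
#' @return List with `expr` (wide expression tibble: `entity_id`, `kind`,
#'   one column per tissue), `pairs` (LUAT-gene id pairs) and `truth`
#'   (planted specificity and correlation).
#' @export
simulate_multitissue <- function(config, seed = config$seed + 3L) {
  tcfg <- config$tissues
  if (tcfg$n < 4) abort("need at least 4 conditions")
  if (abs(tcfg$rho) > 1) abort("|rho| must not exceed 1")
  lay <- sim_layout(config)
  genes <- unique(lay$truth$gene_id[lay$truth$kind == "gene"])
  classes <- lay$truth$class[match(genes, lay$truth$gene_id)]
  luat_genes <- lay$truth$gene_id[lay$truth$kind == "luat"]
  tiss <- sprintf("tissue%02d", seq_len(tcfg$n))
  withr::with_seed(seed, {
    n_g <- length(genes)
    dev <- matrix(rnorm(n_g * tcfg$n), n_g, tcfg$n)
    spec_tissue <- rep(NA_integer_, n_g)
    is_spec <- runif(n_g) < tcfg$specific_fraction
    spec_tissue[is_spec] <- sample.int(tcfg$n, sum(is_spec), replace = TRUE)
    boost <- matrix(0, n_g, tcfg$n)
    boost[cbind(which(is_spec), spec_tissue[is_spec])] <- log(tcfg$boost)
    mu_g <- rnorm(n_g, tcfg$gene_log$meanlog, 0.3)
    glog <- mu_g + tcfg$gene_log$sdlog * dev + boost
    gexpr <- exp(glog)
    # LUATs: correlate with the gene's full (boost-included) log deviations
    li <- match(luat_genes, genes)
    full_dev <- glog[li, , drop = FALSE] -
      rowMeans(glog[li, , drop = FALSE])
    sdev <- full_dev / pmax(apply(full_dev, 1, sd), 1e-12)
    eps <- matrix(rnorm(length(li) * tcfg$n), length(li), tcfg$n)
    eps <- (eps - rowMeans(eps)) / pmax(apply(eps, 1, sd), 1e-12)
    mu_l <- rnorm(length(li), tcfg$luat_log$meanlog, 0.3)
    llog <- mu_l + tcfg$luat_log$sdlog *
      (tcfg$rho * sdev + sqrt(1 - tcfg$rho^2) * eps)
    lexpr <- exp(llog)
  })
  expr <- bind_rows(
    bind_cols(tibble(entity_id = genes, kind = "gene"),
              as_tibble(setNames(as.data.frame(gexpr), tiss))),
    bind_cols(tibble(entity_id = paste0(luat_genes, ".luat"), kind = "luat"),
              as_tibble(setNames(as.data.frame(lexpr), tiss)))
  )
  list(
    expr = expr,
    pairs = tibble(id_a = paste0(luat_genes, ".luat"), id_b = luat_genes),
    truth = tibble(
      entity_id = genes, class = classes,
      specific_tissue = ifelse(is.na(spec_tissue), NA_character_,
                               tiss[spec_tissue])
    )
  )
}
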