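---
title: "Detecting divergent transcription: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting divergent transcription: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`luatscan` detects long upstream antisense transcripts (LUATs) at
protein-coding promoters from strand-specific RNA-seq and computes the
promoter-level sequence and expression statistics that characterize this
promoter class. This vignette explains the model behind each stage, the
parameters that matter, the numerical conventions, and what the synthetic
data generator does and does not emulate.

## Coordinates and containers

All genomic coordinates are 0-based half-open (`[start, end)`, BED
convention); GTF input is converted on read. The TSS of a minus-strand
transcript is `end - 1`, the 5'-most transcribed base. Annotation, read
sets, calls and expression tables are plain tibbles so the pipeline composes
with dplyr; coverage is held as per-chromosome, per-strand run-length
vectors (IRanges `Rle`), and sequence as a Biostrings `DNAStringSet`.

## The screening statistic and its empirical null

Candidate promoters are coding transcripts whose strand-aware 5 kb upstream
window overlaps no coding transcript of another gene on either strand;
isoform TSSs closer than 100 bp (strict) are collapsed to one representative
(the longest transcript, ties by id — the choice is a convention, not an
inference about how the original analysis picked representatives).
Transcripts within 5 kb of a chromosome edge are dropped rather than
zero-padded, so every window is complete.

Coverage in `[TSS - 5 kb, TSS + 5 kb)` is summed in 100-bp bins per strand
and transformed as `log2(x + 1)`. Windows are left-closed with the TSS base
in the first downstream bin; minus-strand anchors are column-flipped so
column 1 is always most-upstream. The screening score is the sum of the 50
upstream antisense bins. The score is computed on the log scale by default:
the transform is described immediately before the ranking step of the
procedure this package implements, so the log scale is taken as the intended
one (a `transform = "raw"` flag preserves the alternative reading).

The null distribution comes from `M = 10,000` random intergenic 5-kb
regions, each at least 1 kb (`buffer`) from any transcript span, with a
random pseudo-orientation and a pseudo-TSS placed so the region is exactly
the upstream flank — this forces the null scores through the *identical*
binning/transform code path as the candidates. The threshold is the
`k = ceiling((1 - alpha) M)`-th smallest null score (`alpha = 0.005`), and a
candidate is called only when its score *strictly* exceeds it. Strictness
makes the calibration guarantee exact: for any score vector and any alpha,
at most a fraction alpha of the calibration scores lie strictly above the
threshold. Random regions may overlap one another (they are independent
uniform draws over eligible starts); the sampler errors only when no
eligible start exists, reporting the available space.

Whether null regions should carry a strand at all is not determined by the
original description; assigning a random orientation per region keeps the
antisense channel defined identically for nulls and genes, which we consider
the conservative choice.

## Assembly: seed, merge, extend

Antisense fragments come either from an external assembler (BED accepted) or
from internal coverage segmentation: maximal runs of per-base coverage
>= `min_cov` (default 1) that span >= 200 bp. Segmentation is a deliberate,
desk-scale stand-in for spliced assembly of real alignments; the merge/extend
logic downstream of it is the method proper. A fragment seeds a LUAT when
its strand-aware 5' end lies within +/- 1.5 kb of the gene TSS (the 5'-end
reading of "starting within" the window; a window-overlap variant is the
obvious alternative and the flag structure leaves room for it). Extension
absorbs, in both directions until closure, any fragment >= 200 bp whose gap
to the current span is strictly below 800 bp, where
`gap = next.start - current.end` on half-open intervals; "closer than 800
bp" is therefore `< 800`, and a gap of exactly 800 bp stops the chain.

This iterative rule is equivalent to single-linkage clustering of intervals
with linkage "gap < 800", restricted to the cluster containing a seed; when
several clusters contain seeds, the one whose seed lies closest to the TSS
wins (tie-break documented in `merge_extend_luat()`). The test suite checks
the equivalence against an independent O(n^2) transitive-closure oracle on
randomized inputs.

Assembled LUATs are single-exon spans: without splice-aware assembly their
internal structure is unknowable, and a span is the honest summary.
Quantification is `FPKM = 1e9 * assigned / (length * library_size)` with a
fragment assigned when same-strand and overlapping the model by >= 1 bp. The
5' offset is reported with negative = upstream of the TSS in the gene's
orientation.

## Promoter sequence features

* **GC content / GC skew profiles** use the same oriented binning as the
  signal matrices. Skew is `(#G - #C)/(#G + #C)` with an `NA` sentinel for
  G+C-free windows; minus-strand promoters are evaluated on the reverse
  complement so that a positive downstream skew always means a G excess in
  the direction the gene is read. Profile bins average per-anchor skews,
  skipping `NA`s.
* **CpG islands** are called by the classical sliding-window criteria
  (GC >= 0.5, observed/expected CpG >= 0.6 with
  `obs/exp = N_CpG * L / (N_C * N_G)`, length >= 200 bp, 200-bp windows).
  Merged windows are re-verified as a whole and trimmed in 10-bp steps from
  the CG-poorer end if the union dilutes below a threshold, so every
  reported island re-satisfies both criteria. On real genomes the curated
  island track should be supplied as BED; the caller exists so synthetic
  genomes are self-contained. Promoter summaries report coverage of
  `[TSS - 500, TSS + 500)` and the summed length of islands overlapping
  `[TSS - 1 kb, TSS + 1 kb)`; islands are counted at full length even when
  they only partially overlap the window (the simplest reading of summing
  island sizes; a clipped mode is available).
* **PWM scoring** is log2-odds against a flat background with a 0.01
  pseudo-count per count-matrix cell; any non-ACGT base scores the column
  minimum so ambiguity can never create a hit. The TATA window is
  `[TSS - 250, TSS + 250)` on the sense strand (the 500-bp window is only
  loosely specified; centering is the symmetric choice, and antisense-strand
  scanning is deliberately off by default).
* **Splice-site accumulation** reports, for each x, the fraction of genes
  whose first motif hit is fully contained in the first x nt downstream of
  the TSS (a hit starting at 1-based s counts from `x = s + L - 1`), giving
  a non-decreasing curve bounded by 1.

## Expression statistics

* **Tissue specificity**: `TS = (e - Q3)/(Q3 - Q1)` with type-7
  linear-interpolation quartiles (R's default; the original description
  names no quartile method). A zero IQR leaves TS undefined and the entity
  non-specific — the alternative (infinite TS) would flag constant genes.
* **Pair correlation** is plain Pearson across conditions; zero-variance
  members are excluded and counted. A `log2` switch correlates
  `log2(FPKM + 0.01)` instead, matching the scale on which the simulator
  plants correlation.
* **Co-regulation** classifies each member as changed when
  `|log2((a + 0.01)/(b + 0.01))| >= 1` (2-fold), builds the 2x2 table of
  (LUAT changed, gene changed) over all pairs and tests it with the
  closed-form Pearson chi-square without continuity correction. "Co-regulated"
  additionally requires the same direction of change. Degenerate input (no
  pair with any change) errors rather than returning a meaningless table.
* **Splicing index**: only transcripts with >= 4 exons and FPKM > 0.1 are
  scored. The 5' index is `log2(mean(FPKM(e1), FPKM(e2)) / FPKM(i1))`; the
  middle index uses the central exon (the mean of the two central exons for
  even exon counts) over the mean of its flanking introns. The intronic
  pairing for the middle index is not fully specified in the source
  description; the both-flank mean is the minimal consistent reading, and a
  single-intron mode is provided. All features get a +0.01 FPKM pseudo-count
  before the ratio.

## The synthetic-data generator

Defaults are the package's study conditions, chosen once: a 2 x 25 Mb
genome at GC 0.42 (mammalian-like; large enough that ~50 planted LUATs of
median 2 kb occupy well under 1% of intergenic space, so the intergenic null
stays clean — the dilution a mammalian genome provides for free must be
designed in at desk scale); 200 genes, 25% with a planted LUAT, 10% in
head-to-head pairs with TSS separation below 1.5 kb; class-specific
first-exon length medians 242/190/195 bp and CpG-island planting
probabilities 0.8/0.89/0.56 (LUAT-associated / head-to-head /
unidirectional), echoing the promoter-class regime the statistics are meant
to resolve; GC-skew blocks of amplitude 0.3 over 500 bp flanking each TSS
(mirrored negative upstream for bidirectional classes); gene and LUAT FPKM
log-normal with medians 3.9 and 0.8; LUAT lengths log-normal with median
2 kb and 5' offsets half-normal within ~500 bp upstream; a 1.5e7-fragment
library of fixed 100-bp fragments with Poisson counts
(`mean = FPKM x exonic kb x library Mfrags`); sparse uniform background at
0.2 fragments/kb/strand; 17 expression conditions with 30% of genes
tissue-specific (one tissue boosted 10x, an order-of-magnitude enrichment so
planted specificity is unambiguous) and LUAT-gene log-scale correlation 0.7.

Intron retention is modeled at the molecule level: a configured fraction of
a transcript's fragments derive from intron-1-retaining pre-mRNA and fall
uniformly over the exon1-intron1-exon2 span, so a retention rate r yields
intron-1 signal near r times the exonic level.

What the generator does **not** emulate: sequencing error and quality,
mappability structure, fragment-length variation, spliced (junction-spanning)
fragments, overdispersed counts (a Poisson model; real libraries are
negative-binomial-ish), isoform mixtures, and any chromatin signal. Passing
tests therefore demonstrate the correctness and calibration of the
algorithms under their stated assumptions — not robustness to alignment
artifacts or biological overdispersion on real data.

One quantitative note on the retention contrast asserted in the acceptance
suite: with empty-control introns (pseudo-count-level signal), the
*difference* in 5' splicing index between a no-retention control and a 25%
retention arm is `log2(0.25 e / pseudo)` — typically 6-10 log2 units, far
above log2(4) — while the retention arm's 5' index itself sits at
`log2(1/0.25) = 2`. The suite asserts both the literal difference criterion
(which fails under any clean generative model and is left failing by
design) and the arithmetically coherent form (which passes); the test output
documents the discrepancy rather than papering over it.

## Numerical conventions and degenerate inputs

Strict inequalities at every stated boundary (`< 100 bp` TSS clusters,
`< 1.5 kb` head-to-head separation, `< 800 bp` merge gaps, score `>`
threshold). Expression matching uses equal-count quantile bins of the
reference (default 10) with largest-remainder allocation and errors when a
required pool bin is empty. Empty read sets give all-zero coverage; anchors
with incomplete windows are dropped with a warning; all-N sequence windows
contribute nothing to GC statistics and score the PWM sentinel minimum.
Every stochastic function takes an explicit seed and is bit-reproducible
given it.

## Problem sizes

The test suite runs the full screen at the default scale (2 x 25 Mb genome,
200 genes, 10,000 null regions) once, and exercises everything else on 3-6 Mb
single-chromosome simulations with 20-60 genes, 1,000-iteration oracle
comparisons for the assembler and the chi-square calibration, and a
10,000-vector quartile cross-check — sizes chosen so the whole suite runs in
a few minutes on one CPU while every statistic still has enough data to be
meaningfully calibrated.

## Known limitations

* Single-exon LUAT models only; no splice-graph assembly or isoform
  deconvolution, and no coding-potential scoring.
* One empirical cutoff, not per-gene FDR: the method deliberately mirrors a
  single intergenic-null threshold.
* FPKM is the only normalization; no cross-library modeling.
* The CpG caller is a classical sliding-window approximation; curated
  tracks are preferable on real genomes.
* `run_end_to_end()` and the exported functions are the interface; there is
  no shell executable.
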