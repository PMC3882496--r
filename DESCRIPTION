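Package: luatscan
Title: Detection and Characterization of Long Upstream Antisense Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects long upstream antisense transcripts (LUATs) at coding-gene
    promoters from strand-specific RNA-seq. Candidate promoters are screened with
    a binned antisense-coverage score calibrated against an empirical null built
    from random intergenic regions; transcript models are assembled by a
    seed/merge/extend algorithm over coverage segments and quantified in FPKM.
    Downstream statistics cover promoter sequence features (GC content and skew,
    CpG islands, TATA-box scores, 5' splice-site accumulation, first-exon length),
    tissue-specificity scores, LUAT-gene co-expression and co-regulation tests,
    and splicing indices quantifying immature transcription. A synthetic-data
    generator produces genomes, annotations, stranded read sets and multi-tissue
    expression tables with planted ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    yaml,
    jsonlite,
    stats,
    methods,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    broom
Config/testthat/edition: 3
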