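Package: lncregnet
Title: Identification of Heat-Responsive lncRNAs and Their Regulatory
    Networks from Plant Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genome-wide analysis of long
    noncoding RNAs (lncRNAs) in stress-treatment transcriptome time
    courses. Screens assembled transcripts with a strict multi-stage
    filter, classifies surviving lncRNAs by genomic position (intergenic,
    intronic, natural antisense), assesses cross-species conservation and
    miRNA-precursor content with a deterministic seeded nucleotide
    aligner, infers cis (genomic proximity) and trans (Pearson
    coexpression) lncRNA-mRNA regulatory edges, predicts miRNA decoy
    (endogenous target mimic) sites with a rule-based bulged-duplex
    search scored by nearest-neighbor hybridization energies, assembles
    competing endogenous RNA (ceRNA) triads, and reports hypergeometric
    functional enrichment. Includes generators for fully synthetic inputs
    with planted ground truth so every stage is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    stringr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
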