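Package: editquant
Title: Quantification of CRISPR-Cas9 Editing Outcomes from Amplicon and
    LMU-PCR Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies in vivo CRISPR-Cas9 editing outcomes at a nuclease
    target locus from paired-end sequencing data. Implements an
    amplicon-sequencing indel-frequency caller (read-pair merging, affine-gap
    local alignment, indel counting in a window around the predicted cleavage
    site) and a ligation-mediated PCR with unique molecular indices (LMU-PCR)
    pipeline for homology-directed-repair (HDR) knock-in quantification (UMI
    extraction, directional unique-molecule identification, mapping-quality /
    length / primer filters, soft-clip classification against a donor- and
    nuclease-vector element panel). A synthetic-data generator builds a target
    locus with homology arms, donor and nuclease vectors, edited-allele
    populations with known truth, and errored paired-end FASTQ libraries for
    both assays, so the whole pipeline can be exercised and verified without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
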