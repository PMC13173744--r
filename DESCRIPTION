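Package: cffrag
Title: Cell-Free DNA Fragmentomics: Length Profiles, End Motifs, and
    Fragmentation Classes from Long-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of circulating cell-free DNA (cfDNA) fragmentation
    from long-read whole-genome sequencing alignments. Computes fragment
    length distributions on a fixed log10 grid in both fragment-count and
    DNA-weighted form, calls adapter-anchored 5' end motifs (CC/CCCA,
    the DNASE1L3 signature), classifies plasma samples into
    hypofragmented, hyperfragmented, ultra-long-contaminated, and
    healthy-like groups by principal component analysis against a healthy
    reference, decomposes circulating DNA concentrations into tumor and
    non-tumor components, and measures fragment-length-stratified tumor
    fraction enrichment. Includes a fully parameterized synthetic cfDNA
    cohort generator with ground truth for end-to-end validation, BAM
    filtering, length stratification, and anonymization utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate: 
    'bam-io.R'
    'cffrag-package.R'
    'end-motif.R'
    'features.R'
    'fragclass.R'
    'log-grid.R'
    'pipeline.R'
    'profile.R'
    'synthetic.R'
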