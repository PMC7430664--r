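Package: pprmotif
Title: Trinucleotide Repeat Motifs and PPR-Code Analysis of Organellar RNA Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating and characterising tandem trinucleotide repeat
    motifs in AU-rich organellar RNAs, built around the recognition site of the
    yeast mitochondrial pentatricopeptide repeat (PPR) protein Dmr1 in 15S
    ribosomal RNA. Provides a maximal period-3 repeat-tract finder with a
    canonical prefix-unit-suffix nomenclature and census, exact motif mapping
    with merging of overlapping matches into loci, overlapping oligonucleotide
    tiling-probe design, a cross-species k-mer presence/absence screen
    constrained by nucleo-mitochondrial compatibility classes, phase-stratified
    amino-acid conservation profiles and information content for PPR motif
    arrays, nucleotide-preference binding profiles derived from a configurable
    PPR code with log-odds scanning of RNA, and seeded synthetic-data
    generators for every input so the whole pipeline is testable without
    downloads. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
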