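Package: viromine
Title: Virome Mining and Mobile Genetic Element Discovery from Assembled Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triaging assembled RNA-seq contigs into RNA virus
    candidates, fungal retroplasmids, group II introns and host transcripts.
    Implements six-frame open reading frame discovery under arbitrary NCBI
    translation tables (including the mold/protozoan mitochondrial code in
    which TGA encodes tryptophan), a coding-system differential that flags
    contigs whose long complete ORFs exist only under the mitochondrial code,
    PROSITE-style protein motif scanning for domain-architecture
    classification (reverse transcriptase, intron maturase, HNH endonuclease,
    RdRP), greedy redundancy clustering at identity/coverage thresholds with
    an exact affine-gap aligner, conserved 5'/3' terminal-motif extraction for
    segmented viruses, and a seeded synthetic contig generator with matching
    similarity-search hit tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
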