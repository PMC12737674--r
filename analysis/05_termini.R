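#!/usr/bin/env Rscript
# Conserved terminal motifs of segmented viruses: for each declared
# segment group the longest strictly shared 5' prefix and 3' suffix are
# extracted and rendered in the RNA alphabet.
#
# Reads results/dataset/, writes results/termini.tsv.

suppressPackageStartupMessages(library(viromine))

contigs <- read_fasta("results/dataset/contigs.fasta")
groups <- readr::read_tsv("results/dataset/segment_groups.tsv",
                          show_col_types = FALSE)

tt <- termini_by_group(contigs, groups)
print(tt, n = Inf)
readr::write_tsv(tt, "results/termini.tsv")
message("wrote results/termini.tsv (", nrow(tt), " segment groups)")
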