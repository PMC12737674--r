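#!/usr/bin/env Rscript
# Generate the synthetic virome used throughout the analysis: labelled
# contigs for seven element classes (host transcripts, mitovirus-like,
# retroplasmid-like, group-II-intron-like, partitivirus-like segment
# trios, host-end chimeras, noncoding) plus the matching protein- and
# nucleotide-level hit tables a similarity search would have produced.
#
# Writes results/dataset/ (FASTA, labels, hit tables, params).

suppressPackageStartupMessages(library(viromine))

seed <- 1L
n_per_class <- 50L

message("simulating dataset: seed ", seed, ", ", n_per_class, " contigs/class")
ds <- make_dataset(seed = seed, n_per_class = n_per_class, mutation_rate = 0)
print(ds)

dir.create("results", showWarnings = FALSE)
write_dataset(ds, "results/dataset")
message("wrote results/dataset/ (",
        nrow(ds$contigs), " contigs, ",
        nrow(ds$protein_hits), " protein hits, ",
        nrow(ds$nucleotide_hits), " nucleotide hits)")
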