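#!/usr/bin/env Rscript
# The coding-system differential and domain-architecture classification:
# contigs whose long complete ORFs appear only under the mitochondrial
# code are scanned for reverse-transcriptase, maturase, HNH and RdRP
# motifs and classified as retroplasmid / group II intron /
# mitovirus-like.
#
# Reads results/dataset/, writes results/coding_calls.tsv and
# results/element_calls.tsv.

suppressPackageStartupMessages(library(viromine))

contigs <- read_fasta("results/dataset/contigs.fasta")
motifs <- default_motifs()

calls <- lapply(seq_len(nrow(contigs)), function(i)
  classify_coding_system(contigs[i, ]))
call_tbl <- coding_calls_tbl(calls)
print(table(call_tbl$call))
readr::write_tsv(call_tbl, "results/coding_calls.tsv")

elements <- lapply(calls, function(cc) {
  ann <- if (cc$call == "mitochondrial_coding" && nrow(cc$mito_orfs))
    dplyr::bind_rows(lapply(cc$mito_orfs$protein, scan_motifs, motifs = motifs))
  else scan_motifs("X", motifs)[0, ]
  classify_element(cc, ann, motifs)
})
elem_tbl <- tibble::tibble(
  contig_id = vapply(elements, function(e) e$contig_id, character(1)),
  element_class = vapply(elements, function(e) e$element_class, character(1)),
  n_motif_hits = vapply(elements, function(e) nrow(e$evidence), integer(1)))
print(table(elem_tbl$element_class))
readr::write_tsv(elem_tbl, "results/element_calls.tsv")
message("wrote results/coding_calls.tsv and results/element_calls.tsv")
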