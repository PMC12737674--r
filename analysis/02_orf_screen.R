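#!/usr/bin/env Rscript
# Six-frame ORF discovery under the standard (table 1) and mold
# mitochondrial (table 4) genetic codes, followed by the triage funnel:
# virus-keyword candidates first, then the three follow-up classes
# (no ORF / ORFs without annotation / divergent non-host best hit),
# everything else host-like; terminal host misassembly is flagged from
# the nucleotide hits.
#
# Reads results/dataset/, writes results/orfs_table{1,4}.gff3,
# results/proteins_table4.faa and results/triage.tsv.

suppressPackageStartupMessages(library(viromine))

contigs <- read_fasta("results/dataset/contigs.fasta")
phits <- read_hit_table("results/dataset/protein_hits.tsv", "outfmt6_extended")
nhits <- read_hit_table("results/dataset/nucleotide_hits.tsv", "outfmt6_extended")

orfs1 <- find_orfs(contigs, genetic_code(1), completeness = "complete")
orfs4 <- find_orfs(contigs, genetic_code(4), completeness = "complete")
message(sprintf("complete ORFs >= 100 aa: %d under table 1, %d under table 4",
                nrow(orfs1), nrow(orfs4)))
write_orfs(orfs1, "results/orfs_table1.gff3")
write_orfs(orfs4, "results/orfs_table4.gff3", "results/proteins_table4.faa")

triage <- triage_contigs(contigs, list(nuclear = orfs1, mito = orfs4),
                         best_hit_per_query(phits),
                         nucleotide_hits = nhits)
print(table(triage$category))
print(table(triage$end_contamination))
readr::write_tsv(triage, "results/triage.tsv")
message("wrote results/triage.tsv")
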