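---
title: "Mining viromes for RNA viruses and mitochondrial mobile elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining viromes for RNA viruses and mitochondrial mobile elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

RNA-seq assemblies of fungi such as *Botrytis cinerea* contain, besides host
transcripts, the genomes of RNA viruses and of virus-adjacent mobile genetic
elements: mitoviruses, partitiviruses, retroplasmids and group II introns.
Only a fraction of these announce themselves through a database hit titled
"virus". The rest hide among contigs with no predicted ORF, ORFs without
functional annotation, or best hits to distant fungi at low identity.
`viromine` implements the desk half of that discovery workflow: it consumes
assembled contigs and the tabular output of a protein/nucleotide similarity
search, and produces a per-contig classification with the evidence attached.
Read trimming, assembly, the similarity searches themselves, phylogenetics
and any wet-lab validation are deliberately upstream or downstream of this
package.

## The coding-system differential

The discriminating observation at the core of the package concerns genetic
codes. Fungal mitochondria translate with the mold mitochondrial code (NCBI
translation table 4), in which TGA encodes tryptophan; in the standard
nuclear code (table 1) TGA is a stop. A mitochondrial element whose protein
uses TGA-tryptophan therefore shows only short, interrupted reading frames
when scanned with table 1, but one long complete ORF when scanned with
table 4. Retroplasmids — fungal mitochondrial elements that encode nothing
but a reverse transcriptase — and mitoviruses both carry this signature.

`find_orfs()` scans all six frames under any registered NCBI table. A
*complete* ORF runs from a start codon to the next in-frame stop; frames
open at a contig edge are reported as 5'-partial, 3'-partial or internal so
that the longest-ORF behaviour of assembly annotation tools remains
recoverable (`require_start = FALSE`). `classify_coding_system()` counts
qualifying ORFs (complete, at least 100 aa by default, matching the `-m
100` convention of common ORF callers) under both tables. Because table 4's
stop set is a subset of table 1's, every table-1 ORF reappears under
table 4 at identical coordinates; only table-4 ORFs *not* reproduced under
table 1 count as mitochondrion-specific evidence, otherwise every host
transcript would trivially qualify. The four calls are `noncoding`,
`nuclear_coding`, `mitochondrial_coding` and `dual_coding`; the paper-style
retroplasmid signature is `mitochondrial_coding` together with the
single-ORF property.

Requiring an explicit ATG start is the stricter, reportable choice; the
start-codon set is configurable per table, and the behaviour when both
codes yield long ORFs (our `dual_coding`) is flagged rather than silently
resolved, since the upstream literature does not define it.

## Triage

`triage_contigs()` applies a fixed precedence per contig: a best hit whose
title contains "virus" (case-insensitively, including inside words such as
"mitovirus") wins immediately; then contigs with no qualifying ORF under
any configured table; then contigs with ORFs but no hit at all; then
contigs whose best hit is neither the host organism nor a configured
related species *and* falls below 90% amino-acid identity; everything else
is host-like. "Best hit" is the lowest e-value, with bitscore, identity and
subject id as deterministic tie-breaks.

Host sequence misassembled onto the end of a viral contig is flagged by
`flag_end_contamination()`: a host-organism nucleotide hit at or above 90%
identity that covers at least half of a terminal window (20% of the contig
length) without crossing the contig midpoint marks that end for trimming.
The window fraction, coverage requirement and identity floor are
configuration, not biology: the source workflow performed this step
manually and quantified nothing, so the defaults are chosen to catch a
300 nt misassembled block on a 1-3 kb contig while ignoring whole-contig
host similarity, and they are recorded in every report.

## Domain architectures

Mitochondrially coded proteins are classified by motif content
(`scan_motifs()`, `classify_element()`): reverse transcriptase plus
maturase or HNH endonuclease evidence means group II intron; reverse
transcriptase alone on a single-ORF element means retroplasmid; an RdRP
core means mitovirus-like. The precedence is total, so maturase/HNH
evidence always outranks the retroplasmid call. Motif definitions are
PROSITE-style patterns in configuration — the defaults ship the canonical
reverse-transcriptase YxDD box generalised to `[YF]-x-D-D`, a maturase
placeholder, an HNH placeholder and the RdRP `G-D-D` triad — because the
original discovery used interactive profile-search servers that a
reproducible offline pipeline cannot call. The synthetic generator plants
exactly the configured realizations, so the classification tests are
self-consistent; passing them demonstrates the plumbing and the precedence
logic, not fidelity to Pfam profile HMMs on real proteins.

## Redundancy clustering

`greedy_cluster()` collapses near-identical sequences CD-HIT-style: sort by
length descending, join the earliest representative matched at both
thresholds (95% identity, 95% coverage by default), else found a new
cluster. Identity and coverage come from an affine-gap dovetail alignment
(match +1, mismatch −1, gap open −2, gap extend −1; a gap of length *k*
costs open + *k*·extend). Identity is matches over aligned columns
excluding terminal overhangs; coverage is computed on the **shorter**
sequence, the convention that makes a fragment redundant with the full
element it came from. Co-optimal alignments are resolved by a fixed
lexicographic objective — score, then matches, then fewest columns, then
longest span — so every reported number is deterministic and the aligner
can be validated cell-for-cell against an independent full-matrix oracle
and, on tiny inputs, against exhaustive enumeration of all alignments.
Greedy longest-first clustering rather than exact clique partitioning is
the standard, order-stable choice; exact partitioning is exponential and
nothing upstream implies it.

## Terminal motifs

Genome segments of a partitivirus share short, strictly conserved 5' and 3'
termini. `conserved_termini()` returns the longest prefix (and suffix)
whose per-column majority consensus every segment matches within a
substitution budget; the default budget of 0 makes it the exact longest
common prefix/suffix, which is what cloned segment sets show. A length cap
(30 nt) prevents identical inputs from producing a degenerate
whole-sequence consensus. Output is rendered with U, as segmented RNA virus
termini are conventionally written; storage stays in the DNA alphabet.

## The synthetic virome

`make_dataset()` generates the study conditions every stage is tested
under: for each class it constructs sequences whose class-defining
properties hold *by construction* and verifies them with the package's own
classifiers, regenerating (bounded retries) any draw spoiled by flanking
randomness.

* **H** — host transcript: one standard-code ORF of at least 120 aa with no
  internal TGA, plus a host-organism protein hit near 97% identity.
* **R** — retroplasmid-like: a single 300+ aa ORF readable only under
  table 4 (tryptophans encoded as TGA every 50-70 codons keep every
  standard-code frame below 100 aa), carrying the configured
  reverse-transcriptase motif, with a divergent (40-60% identity) non-host
  hit — the situation in which a real retroplasmid surfaces in a search
  against a protein database.
* **M** — mitovirus-like: as R but with the RdRP motif and a virus-titled
  hit.
* **G2** — group-II-intron-like: reverse transcriptase + maturase + HNH
  motifs in one mitochondrial ORF.
* **P** — partitivirus-like segment sets sharing exact 5'/3' termini
  (defaults GCGCAAA / AATCC) and diverging immediately inside them, so the
  conserved region is maximal by construction; segments travel in groups
  of three (a remainder folds into a final group of two or four).
* **C** — a host transcript with a 300 nt host block misassembled onto one
  end and a matching terminal nucleotide hit.
* **N** — noncoding random sequence, rejection-sampled until no qualifying
  ORF exists under either table.

All randomness flows from a single seed; regeneration from (seed, params)
is byte-identical. Point mutation at a configurable rate is applied after
construction, and the class-defining invariants are re-checked — a contig
that loses them is regenerated. This makes the generator's guarantee
explicit: planted classes survive the configured noise level by
construction, so full-pipeline recovery on the synthetic data is a test of
the pipeline's logic, not of the generator's luck. For the P class the
terminal motif positions are exempt from mutation, since the shared
termini are the group-level defining property. What the generator does
*not* emulate: phylogenetically realistic divergence, indels, assembly
chimerism beyond the single terminal block, codon-usage bias, or Pfam-grade
domain models — conclusions about real viromes still require the real
searches the pipeline's inputs come from.

`make_redundant_set()` builds the clustering condition: 15 distinct
elements (500-900 nt) plus 109 copies at up to 3% substitution divergence
with a few nucleotides trimmed from the ends, so copies are strictly
shorter than their seed and the seeds found the clusters under
longest-first order.

## Problem sizes and numerical choices

The bundled analysis scripts and tests run the full pipeline at 50 contigs
per class (about 350 contigs), the clustering experiment at 124 sequences,
and validate the ORF scanner against a brute-force enumerator on 200
random 600 nt contigs — sizes chosen so the whole analysis reruns from
scratch in minutes on a laptop while still exercising every rule at the
thresholds stated above. Ties are broken deterministically everywhere
(lexicographic ids in clustering order, alphabetical majority in terminal
consensus, fixed precedence in classification), so repeated runs are
byte-identical. Degenerate inputs — empty contig sets, hit tables
referencing unknown contigs, single-segment groups, malformed motif
patterns — fail loudly at the stage that detects them.

## Known limitations

The motif layer is a pattern matcher, not a profile HMM; real domain
annotation should come from profile searches whose tabular output can be
mapped onto the same motif names. The 90% identity and 95/95 redundancy
thresholds are taken from the source workflow's description and applied
exactly; no sensitivity analysis is attempted. The end-contamination
window parameters are this package's own operationalisation of a manual
step. Phylogenetic placement, which the source workflow used to relate
retroplasmid clades, is out of scope.
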