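# Seeded generator of labelled contigs and matching similarity-search hit
# tables, emulating the input structure the triage stages assume.
#
# Classes:
#   H  nuclear-coding host transcript (one standard-code ORF, host hit)
#   M  mitovirus-like element (mito-code-only ORF with RdRP motif,
#      virus-titled hit)
#   R  retroplasmid-like element (single mito-code-only ORF carrying the
#      reverse-transcriptase motif, divergent non-host hit)
#   G2 group-II-intron-like element (mito-code ORF with RT + maturase +
#      HNH motifs, divergent non-host hit)
#   P  partitivirus-like genome segments sharing 5'/3' termini,
#      virus-titled hits
#   C  host transcript with a host block misassembled at one end plus a
#      matching terminal nucleotide hit
#   N  noncoding random sequence, no hits
#
# All randomness flows from one seed; regeneration from (seed, params) is
# byte-identical.  Class-defining invariants are re-checked after point
# mutation; a contig that loses them is regenerated (bounded retries).

SYNTH_CLASSES <- c("H", "M", "R", "G2", "P", "C", "N")

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

#' Point-mutate a sequence
#'
#' Independent per-site substitution to a uniformly chosen different base.
#'
#' @param sequence DNA string.
#' @param rate per-site substitution probability in [0, 1).
#' @param seed optional seed; when NULL the current RNG stream is used
#'   (as inside [make_dataset()]).
#' @param protect 1-based positions exempt from mutation.
#' @return mutated sequence.
#' @export
mutate_sequence <- function(sequence, rate, seed = NULL, protect = integer(0)) {
  stopifnot(rate >= 0, rate < 1)
  if (!is.null(seed)) return(withr::with_seed(seed, mutate_sequence(sequence, rate,
                                                                    protect = protect)))
  if (rate == 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  hit <- which(runif(length(chars)) < rate & chars %in% c("A", "C", "G", "T"))
  hit <- setdiff(hit, protect)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_protein <- function(n, exclude = character(0)) {
  paste(sample(setdiff(AA20, exclude), n, replace = TRUE), collapse = "")
}

# Encode a protein as DNA under a genetic code; W is encoded as TGA when
# use_tga_trp (the table-4 signature), TGG otherwise.
encode_protein <- function(protein, code, use_tga_trp = FALSE) {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- names(code$codon_map)[code$codon_map == a]
    if (a == "W") opts <- if (use_tga_trp) "TGA" else "TGG"
    if (!length(opts)) stop("no codon for residue ", a)
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
  paste(codons, collapse = "")
}

# Plant a subsequence at a given aa position (1-based), overwriting.
plant <- function(protein, motif, pos) {
  paste0(substr(protein, 1, pos - 1), motif,
         substr(protein, pos + nchar(motif), nchar(protein)))
}

# Sprinkle tryptophans so that in-frame TGA codons recur at most `gap`
# codons apart, truncating standard-code reading below the ORF threshold.
sprinkle_trp <- function(protein, gap = 70L, margin = 5L) {
  n <- nchar(protein)
  pos <- seq.int(margin + sample.int(20L, 1L), n - margin, by = gap)
  for (p in pos) protein <- plant(protein, "W", p)
  protein
}

motif_by_name <- function(motifs, name) {
  m <- Filter(function(x) x$name == name, motifs)
  if (!length(m)) stop("motif not configured: ", name)
  m[[1]]
}

motif_presence <- function(protein, motifs) {
  ann <- scan_motifs(protein, motifs)
  stats::setNames(vapply(motifs, function(m)
    sum(ann$motif_name == m$name) >= (m$min_score %||% 1L), logical(1)),
    vapply(motifs, `[[`, character(1), "name"))
}

new_hit <- function(query_id, subject_id, title, organism, identity,
                    qlen, evalue, bitscore, query_coverage = NULL,
                    query_start = NULL, query_end = NULL) {
  alen <- max(1L, round(qlen * (query_coverage %||% runif(1, 90, 100)) / 100))
  qs <- query_start %||% 1L
  qe <- query_end %||% (qs + alen - 1L)
  tibble::tibble(query_id = query_id, subject_id = subject_id,
                 percent_identity = round(identity, 1),
                 alignment_length = as.integer(alen),
                 mismatches = as.integer(round(alen * (100 - identity) / 100)),
                 gap_opens = 0L,
                 query_start = as.integer(qs), query_end = as.integer(qe),
                 subject_start = 1L, subject_end = as.integer(alen),
                 evalue = evalue, bitscore = bitscore,
                 query_coverage = round(query_coverage %||% (100 * alen / qlen), 1),
                 subject_title = title, subject_organism = organism)
}

# ---- per-class constructors -------------------------------------------------

synth_check_env <- function(motifs, min_len_aa = 100L) {
  list(motifs = motifs, min_len_aa = min_len_aa)
}

check_class <- function(class, sequence, id, env) {
  cc <- classify_coding_system(stats::setNames(sequence, id),
                               min_len_aa = env$min_len_aa)
  scan_mito <- function() {
    prots <- cc$mito_orfs$protein
    if (!length(prots)) return(stats::setNames(logical(length(env$motifs)),
                                               vapply(env$motifs, `[[`, character(1), "name")))
    pres <- lapply(prots, motif_presence, motifs = env$motifs)
    Reduce(`|`, pres)
  }
  switch(class,
    H = cc$call == "nuclear_coding" && cc$longest_aa_table1 >= 120L,
    C = cc$call == "nuclear_coding" && cc$longest_aa_table1 >= 120L,
    N = cc$n_orfs_table1 == 0L && cc$n_orfs_table4 == 0L,
    R = {
      p <- scan_mito()
      cc$call == "mitochondrial_coding" && isTRUE(cc$single_orf) &&
        cc$longest_aa_table4 >= 300L &&
        p[["RVT_1"]] && !p[["Intron_maturas2"]] && !p[["AI2M_like_HNH"]]
    },
    M = {
      p <- scan_mito()
      cc$call == "mitochondrial_coding" && p[["RdRP_core"]] && !p[["RVT_1"]]
    },
    G2 = {
      p <- scan_mito()
      cc$call == "mitochondrial_coding" && p[["RVT_1"]] &&
        p[["Intron_maturas2"]] && p[["AI2M_like_HNH"]]
    },
    # P is defined by its shared termini and virus-titled hit; the coding
    # check only excludes a mitochondrial call so triage/differential
    # cannot confuse it with a mitochondrial element
    P = cc$call != "mitochondrial_coding",
    stop("unknown class ", class))
}

with_retries <- function(n, what, f) {
  for (attempt in seq_len(n)) {
    out <- f()
    if (!is.null(out)) return(out)
  }
  stop("synthetic generator: could not satisfy constraints for ", what,
       " within ", n, " attempts")
}

gen_body_H <- function(env) {
  n_aa <- sample(120:240, 1)
  prot <- paste0("M", random_protein(n_aa - 1))
  paste0(random_dna(sample(20:50, 1)), "ATG",
         encode_protein(substr(prot, 2, n_aa), genetic_code(1L)),
         sample(c("TAA", "TAG"), 1), random_dna(sample(20:50, 1)))
}

gen_H <- function(id, env, rate, retries = 200L) {
  with_retries(retries, paste("class H contig", id), function() {
    seq <- gen_body_H(env)
    seq <- mutate_sequence(seq, rate)
    if (!check_class("H", seq, id, env)) return(NULL)
    hit <- new_hit(id, sprintf("XP_%06d.1", sample.int(999999L, 1)),
                   sprintf("hypothetical protein BCIN_%05d [Botrytis cinerea]",
                           sample.int(99999L, 1)),
                   "Botrytis cinerea", identity = min(99.9, rnorm(1, 97, 1)),
                   qlen = nchar(seq), evalue = 10^-runif(1, 80, 150),
                   bitscore = round(runif(1, 200, 600)))
    list(sequence = seq, protein_hits = hit, nt_hits = NULL)
  })
}

gen_mito_protein <- function(n_aa, plants, exclude = character(0)) {
  # plants: named list motif-realization -> relative position in (0,1)
  prot <- random_protein(n_aa, exclude = exclude)
  prot <- sprinkle_trp(prot, gap = sample(50:70, 1))
  for (nm in names(plants)) {
    pos <- max(2L, min(n_aa - nchar(plants[[nm]]) - 1L,
                       round(as.numeric(nm) * n_aa)))
    prot <- plant(prot, plants[[nm]], pos)
  }
  prot
}

mito_contig <- function(prot) {
  paste0(random_dna(sample(15:40, 1)), "ATG",
         encode_protein(prot, genetic_code(4L), use_tga_trp = TRUE),
         "TAA", random_dna(sample(15:40, 1)))
}

gen_R <- function(id, env, rate, retries = 500L) {
  rvt <- motif_by_name(env$motifs, "RVT_1")$realization
  with_retries(retries, paste("class R contig", id), function() {
    prot <- gen_mito_protein(sample(300:460, 1),
                             plants = stats::setNames(list(rvt), "0.45"))
    seq <- mutate_sequence(mito_contig(prot), rate)
    if (!check_class("R", seq, id, env)) return(NULL)
    hit <- new_hit(id, "AAF89327.2",
                   "hypothetical protein [Trichoderma harzianum]",
                   "Trichoderma harzianum", identity = runif(1, 40, 60),
                   qlen = nchar(seq), evalue = 10^-runif(1, 20, 60),
                   bitscore = round(runif(1, 80, 250)))
    list(sequence = seq, protein_hits = hit, nt_hits = NULL)
  })
}

MITOVIRUS_SUBJECTS <- data.frame(
  acc = c("MT119677", "MT089704", "NC_076556", "ON738336"),
  title = c("Botrytis cinerea mitovirus 1 isolate BCS1_DN4879, complete genome",
            "Botrytis cinerea mitovirus 9 isolate BCS1_DN2958, complete genome",
            "Sclerotinia sclerotiorum mitovirus 3, complete genome",
            "Botrytis cinerea mitovirus 3 isolate VPS3, complete genome"),
  organism = c("Botrytis cinerea mitovirus 1", "Botrytis cinerea mitovirus 9",
               "Sclerotinia sclerotiorum mitovirus 3",
               "Botrytis cinerea mitovirus 3"))

gen_M <- function(id, env, rate, retries = 500L) {
  gdd <- motif_by_name(env$motifs, "RdRP_core")$realization
  with_retries(retries, paste("class M contig", id), function() {
    n_aa <- sample(250:400, 1)
    prot <- gen_mito_protein(n_aa, plants = list(), exclude = character(0))
    # plant RdRP core with a non-[YF] residue in front so the RT pattern
    # cannot fire on the planted site
    pos <- max(3L, round(0.6 * n_aa))
    prot <- plant(prot, paste0("A", gdd), pos - 1L)
    seq <- mutate_sequence(mito_contig(prot), rate)
    if (!check_class("M", seq, id, env)) return(NULL)
    subj <- MITOVIRUS_SUBJECTS[sample.int(nrow(MITOVIRUS_SUBJECTS), 1), ]
    hit <- new_hit(id, subj$acc, subj$title, subj$organism,
                   identity = runif(1, 85, 99), qlen = nchar(seq),
                   evalue = 10^-runif(1, 60, 150),
                   bitscore = round(runif(1, 200, 500)))
    list(sequence = seq, protein_hits = hit, nt_hits = NULL)
  })
}

gen_G2 <- function(id, env, rate, retries = 500L) {
  rvt <- motif_by_name(env$motifs, "RVT_1")$realization
  mat <- motif_by_name(env$motifs, "Intron_maturas2")$realization
  hnh <- motif_by_name(env$motifs, "AI2M_like_HNH")$realization
  with_retries(retries, paste("class G2 contig", id), function() {
    prot <- gen_mito_protein(sample(450:650, 1),
                             plants = stats::setNames(list(rvt, mat, hnh),
                                                      c("0.25", "0.55", "0.8")))
    seq <- mutate_sequence(mito_contig(prot), rate)
    if (!check_class("G2", seq, id, env)) return(NULL)
    hit <- new_hit(id, "YP_010836049.1",
                   "hypothetical protein [Phyllosticta yuccae]",
                   "Phyllosticta yuccae", identity = runif(1, 70, 85),
                   qlen = nchar(seq), evalue = 10^-runif(1, 40, 100),
                   bitscore = round(runif(1, 150, 400)))
    list(sequence = seq, protein_hits = hit, nt_hits = NULL)
  })
}

gen_C <- function(id, env, rate, retries = 200L) {
  with_retries(retries, paste("class C contig", id), function() {
    body <- gen_body_H(env)
    block <- random_dna(300L)
    side <- sample(c("left", "right"), 1)
    seq <- if (side == "left") paste0(block, body) else paste0(body, block)
    protect <- integer(0)
    seq <- mutate_sequence(seq, rate)
    if (!check_class("C", seq, id, env)) return(NULL)
    L <- nchar(seq)
    if (side == "left") { qs <- 1L; qe <- 300L } else { qs <- L - 299L; qe <- L }
    flag <- flag_end_contamination(stats::setNames(seq, id),
                                   new_hit(id, "Bcin_scaffold_12",
                                           "Botrytis cinerea genomic scaffold",
                                           "Botrytis cinerea", 99,
                                           qlen = L, evalue = 0, bitscore = 500,
                                           query_start = qs, query_end = qe))$flag
    if (flag != side) return(NULL)
    prot_hit <- new_hit(id, sprintf("XP_%06d.1", sample.int(999999L, 1)),
                        sprintf("hypothetical protein BCIN_%05d [Botrytis cinerea]",
                                sample.int(99999L, 1)),
                        "Botrytis cinerea", identity = min(99.9, rnorm(1, 97, 1)),
                        qlen = L, evalue = 10^-runif(1, 80, 150),
                        bitscore = round(runif(1, 200, 600)))
    nt_hit <- new_hit(id, "Bcin_scaffold_12",
                      "Botrytis cinerea genomic scaffold",
                      "Botrytis cinerea", identity = runif(1, 97, 100),
                      qlen = L, evalue = 0, bitscore = round(runif(1, 400, 600)),
                      query_start = qs, query_end = qe)
    list(sequence = seq, protein_hits = prot_hit, nt_hits = nt_hit)
  })
}

gen_N <- function(id, env, rate, retries = 200L) {
  with_retries(retries, paste("class N contig", id), function() {
    seq <- mutate_sequence(random_dna(sample(200:420, 1)), rate)
    if (!check_class("N", seq, id, env)) return(NULL)
    list(sequence = seq, protein_hits = NULL, nt_hits = NULL)
  })
}

PARTITIVIRUS_SUBJECTS <- data.frame(
  acc = c("MN954881", "MN954882", "MF444214"),
  title = c("Botryotinia fuckeliana partitivirus 1 isolate BCS3_DN4616 segment RNA1",
            "Botryotinia fuckeliana partitivirus 1 isolate BCI12_DN10399 segment RNA2",
            "Sclerotinia sclerotiorum partitivirus 3 isolate SsPV3 RdRP gene"),
  organism = c("Botryotinia fuckeliana partitivirus 1",
               "Botryotinia fuckeliana partitivirus 1",
               "Sclerotinia sclerotiorum partitivirus 3"))

#' Build one partitivirus-like segment set with shared termini
#'
#' Segments share an exact 5' prefix and 3' suffix and diverge immediately
#' inside them (so the conserved region is maximal by construction); each
#' segment carries one standard-code ORF.
#'
#' @param n_segments segments in the set (>= 2).
#' @param five_prime,three_prime shared termini, DNA alphabet.
#' @param env internal check environment (motif config + ORF threshold).
#' @param rate point-mutation rate; terminal motif positions are exempt so
#'   the group-defining invariant survives mutation.
#' @param ids segment ids.
#' @param retries attempts before giving up.
#' @return named character vector of segment sequences.
#' @export
make_segment_set <- function(n_segments = 3L, five_prime = "GCGCAAA",
                             three_prime = "AATCC",
                             env = synth_check_env(default_motifs()),
                             rate = 0, ids = paste0("seg", seq_len(n_segments)),
                             retries = 300L) {
  five_prime <- normalize_sequence(five_prime)
  three_prime <- normalize_sequence(three_prime)
  with_retries(10L, "partitivirus segment set", function() {
    # divergence bases directly inside the shared termini: guarantee at
    # least two distinct letters across segments at each junction
    div5 <- rep_len(sample(c("A", "C", "G")), n_segments)
    div3 <- rep_len(sample(c("C", "G", "T")), n_segments)
    seqs <- vapply(seq_len(n_segments), function(k) {
      with_retries(retries, paste("partitivirus segment", ids[k]), function() {
        n_aa <- sample(280:420, 1)
        prot <- paste0("M", random_protein(n_aa - 1))
        s <- paste0(five_prime, div5[k], random_dna(sample(25:60, 1)),
                    "ATG", encode_protein(substr(prot, 2, n_aa), genetic_code(1L)),
                    sample(c("TAA", "TAG"), 1),
                    random_dna(sample(25:60, 1)), div3[k], three_prime)
        if (rate > 0) {
          L <- nchar(s)
          s <- mutate_sequence(s, rate,
                               protect = c(seq_len(nchar(five_prime) + 1L),
                                           (L - nchar(three_prime)):L))
        }
        if (!check_class("P", s, ids[k], env)) return(NULL)
        s
      })
    }, character(1))
    names(seqs) <- ids
    tc <- conserved_termini(seqs, max_mismatch = 0L)
    if (tc$five_prime != chartr("T", "U", five_prime) ||
        tc$three_prime != chartr("T", "U", three_prime)) return(NULL)
    seqs
  })
}

gen_P_groups <- function(n, env, rate, five_prime, three_prime, id_prefix = "PV") {
  # partition n segments into groups of 3 (remainder folded into a final
  # group of 2 or 4 so every group supports a consensus)
  sizes <- rep(3L, n %/% 3L)
  r <- n %% 3L
  if (r == 1L) {
    if (length(sizes)) sizes[length(sizes)] <- 4L else sizes <- 1L
  } else if (r == 2L) sizes <- c(sizes, 2L)
  if (any(sizes < 2L)) stop("class P needs at least 2 segments")
  contigs <- list(); hits <- list(); groups <- list()
  for (g in seq_along(sizes)) {
    vid <- sprintf("%s%02d", id_prefix, g)
    ids <- sprintf("%s_seg%d", vid, seq_len(sizes[g]))
    seqs <- make_segment_set(sizes[g], five_prime, three_prime, env, rate, ids)
    for (k in seq_along(ids)) {
      subj <- PARTITIVIRUS_SUBJECTS[sample.int(nrow(PARTITIVIRUS_SUBJECTS), 1), ]
      hits[[length(hits) + 1L]] <-
        new_hit(ids[k], subj$acc, subj$title, subj$organism,
                identity = runif(1, 88, 99), qlen = nchar(seqs[[k]]),
                evalue = 10^-runif(1, 60, 150),
                bitscore = round(runif(1, 200, 500)))
    }
    contigs[[g]] <- seqs
    groups[[g]] <- tibble::tibble(virus_id = vid, contig_id = ids)
  }
  list(sequences = unlist(contigs), protein_hits = dplyr::bind_rows(hits),
       segment_groups = dplyr::bind_rows(groups))
}

# ---- dataset assembly -------------------------------------------------------

#' Generate a labelled synthetic dataset
#'
#' @param seed integer seed; regeneration from the same (seed, params) is
#'   byte-identical.
#' @param n_per_class contigs per class: a single count or a named vector
#'   over `r paste(SYNTH_CLASSES, collapse=", ")`.
#' @param mutation_rate per-site substitution rate in [0, 0.25) applied
#'   after construction; class-defining invariants are re-checked and the
#'   contig regenerated if they were destroyed.
#' @param motif_config motif definitions; the generator plants exactly the
#'   configured realizations.
#' @param min_len_aa qualifying-ORF threshold used by the invariant checks.
#' @param termini_5,termini_3 shared termini for P-class segment sets.
#' @return list of class `synthetic_dataset`: contigs, labels,
#'   protein_hits, nucleotide_hits, segment_groups, seed, params.
#' @export
make_dataset <- function(seed, n_per_class = 5L, mutation_rate = 0,
                         motif_config = default_motifs(),
                         min_len_aa = 100L,
                         termini_5 = "GCGCAAA", termini_3 = "AATCC") {
  stopifnot(mutation_rate >= 0, mutation_rate < 0.25)
  if (length(n_per_class) == 1L && is.null(names(n_per_class)))
    n_per_class <- stats::setNames(rep(as.integer(n_per_class),
                                       length(SYNTH_CLASSES)), SYNTH_CLASSES)
  stopifnot(all(names(n_per_class) %in% SYNTH_CLASSES), all(n_per_class >= 0))
  params <- list(n_per_class = as.list(n_per_class),
                 mutation_rate = mutation_rate, min_len_aa = min_len_aa,
                 termini_5 = termini_5, termini_3 = termini_3)
  env <- synth_check_env(motif_config, min_len_aa)
  npc <- function(cl) if (cl %in% names(n_per_class)) n_per_class[[cl]] else 0L

  withr::with_seed(as.integer(seed), {
    seqs <- character(0); labels <- character(0)
    phits <- list(); nhits <- list()
    seg_groups <- tibble::tibble(virus_id = character(), contig_id = character())

    gen_simple <- function(class, gen) {
      n <- npc(class)
      for (i in seq_len(n)) {
        id <- sprintf("%s%03d", class, i)
        out <- gen(id, env, mutation_rate)
        seqs[[id]] <<- out$sequence
        labels[[id]] <<- class
        if (!is.null(out$protein_hits)) phits[[length(phits) + 1L]] <<- out$protein_hits
        if (!is.null(out$nt_hits)) nhits[[length(nhits) + 1L]] <<- out$nt_hits
      }
    }
    gen_simple("H", gen_H)
    gen_simple("M", gen_M)
    gen_simple("R", gen_R)
    gen_simple("G2", gen_G2)
    nP <- npc("P")
    if (nP > 0) {
      pg <- gen_P_groups(nP, env, mutation_rate, termini_5, termini_3)
      for (id in names(pg$sequences)) {
        seqs[[id]] <- pg$sequences[[id]]
        labels[[id]] <- "P"
      }
      phits[[length(phits) + 1L]] <- pg$protein_hits
      seg_groups <- pg$segment_groups
    }
    gen_simple("C", gen_C)
    gen_simple("N", gen_N)

    structure(list(
      contigs = new_contig_tbl(names(seqs), unname(unlist(seqs))),
      labels = tibble::tibble(contig_id = names(labels),
                              class = unname(unlist(labels))),
      protein_hits = if (length(phits)) dplyr::bind_rows(phits) else empty_hit_tbl(),
      nucleotide_hits = if (length(nhits)) dplyr::bind_rows(nhits) else empty_hit_tbl(),
      segment_groups = seg_groups,
      seed = as.integer(seed), params = params),
      class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> seed %d: %d contigs (%s)\n", x$seed,
              nrow(x$contigs),
              paste(sprintf("%s=%d", names(table(x$labels$class)),
                            table(x$labels$class)), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits contigs FASTA, labels TSV, the two hit tables (extended outfmt-6
#' TSV), segment-group TSV and a params JSON sufficient to regenerate.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$contigs, file.path(dir, "contigs.fasta"))
  readr::write_tsv(dataset$labels, file.path(dir, "labels.tsv"))
  write_hit_table(dataset$protein_hits, file.path(dir, "protein_hits.tsv"))
  write_hit_table(dataset$nucleotide_hits, file.path(dir, "nucleotide_hits.tsv"))
  readr::write_tsv(dataset$segment_groups, file.path(dir, "segment_groups.tsv"))
  jsonlite::write_json(c(list(seed = dataset$seed), dataset$params),
                       file.path(dir, "params.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Generate a redundant sequence set with known cluster structure
#'
#' Seed sequences plus mutated, lightly end-trimmed copies (bounded
#' divergence), mirroring a redundancy-removal experiment where a known
#' number of distinct elements is recovered from a larger pile of
#' near-identical database contigs.  Copies are strictly shorter than
#' their seed so the seeds found the clusters under longest-first greedy
#' clustering.
#'
#' @param seed RNG seed.
#' @param n_seeds distinct source sequences.
#' @param n_copies total mutated copies distributed over the seeds.
#' @param len_range seed length range (nt).
#' @param max_divergence upper bound on per-site substitution rate.
#' @return list: `sequences` (named vector, seeds then copies),
#'   `truth` tibble (member_id, seed_id).
#' @export
make_redundant_set <- function(seed, n_seeds = 15L, n_copies = 109L,
                               len_range = c(500L, 900L), max_divergence = 0.03) {
  withr::with_seed(as.integer(seed), {
    seeds <- stats::setNames(
      vapply(seq_len(n_seeds), function(i)
        random_dna(sample(len_range[1]:len_range[2], 1)), character(1)),
      sprintf("elem%02d", seq_len(n_seeds)))
    copies <- character(0)
    truth <- tibble::tibble(member_id = names(seeds), seed_id = names(seeds))
    for (k in seq_len(n_copies)) {
      src <- sample(n_seeds, 1)
      rate <- runif(1, 0.002, max_divergence * 0.8)
      repeat {
        s <- mutate_sequence(seeds[[src]], rate)
        lt <- sample(1:6, 1); rt <- sample(0:6, 1)
        s <- substr(s, 1 + lt, nchar(s) - rt)
        st <- pairwise_stats(s, seeds[[src]])
        if (st$identity >= 95 && st$coverage >= 95) break
      }
      id <- sprintf("%s_copy%03d", names(seeds)[src], k)
      copies[[id]] <- s
      truth <- dplyr::bind_rows(truth,
                                tibble::tibble(member_id = id,
                                               seed_id = names(seeds)[src]))
    }
    list(sequences = c(seeds, unlist(copies)), truth = truth)
  })
}
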