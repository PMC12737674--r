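# Codon-table registry and six-frame ORF discovery.
#
# The discriminating fact this module exists for: under NCBI translation
# table 1 TGA is a stop codon, under table 4 (mold/protozoan mitochondrial,
# the code fungal mitochondria use) TGA encodes tryptophan.  Mitochondrial
# mobile elements therefore present long complete ORFs only when scanned
# with table 4.

#' Construct a genetic code from the NCBI registry
#'
#' Tables are taken from the NCBI translation-table registry shipped with
#' Biostrings; any registered table id works, with 1 (standard) and 4
#' (mold/protozoan mitochondrial) being the ones the pipeline uses.
#'
#' @param table_id NCBI translation table id (integer or string).
#' @param start_codons set of codons accepted as ORF starts. The default,
#'   ATG only, is the strict reportable choice; widen it (e.g. to the NCBI
#'   alternative initiators) via configuration.
#' @return object of class `genetic_code`: list with `table_id`,
#'   `codon_map` (64 codons to single-letter amino acid, `*` = stop),
#'   `start_codons`, `stop_codons`.
#' @export
.code_cache <- new.env(parent = emptyenv())

genetic_code <- function(table_id = 1L, start_codons = "ATG") {
  key <- paste(table_id, paste(start_codons, collapse = ","))
  hit <- .code_cache[[key]]
  if (!is.null(hit)) return(hit)
  map <- tryCatch(Biostrings::getGeneticCode(as.character(table_id)),
                  error = function(e) stop("unknown NCBI translation table: ", table_id,
                                           call. = FALSE))
  map <- map[order(names(map))]
  stopifnot(length(map) == 64L)
  start_codons <- toupper(start_codons)
  if (!all(start_codons %in% names(map))) stop("invalid start codon")
  out <- structure(list(table_id = as.integer(table_id),
                        codon_map = map,
                        start_codons = start_codons,
                        stop_codons = names(map)[map == "*"]),
                   class = "genetic_code")
  .code_cache[[key]] <- out
  out
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> NCBI table %d; stops: %s; starts: %s\n",
              x$table_id, paste(x$stop_codons, collapse = ","),
              paste(x$start_codons, collapse = ",")))
  invisible(x)
}

#' Load genetic codes from a YAML config file
#'
#' The file holds a list of entries with fields `table_id` and optionally
#' `start_codons`; each entry is resolved against the NCBI registry.
#'
#' @param path YAML file.
#' @return named list of `genetic_code` objects keyed by table id.
#' @export
load_genetic_codes <- function(path) {
  cfg <- yaml::read_yaml(path)
  codes <- lapply(cfg, function(e)
    genetic_code(e$table_id, start_codons = e$start_codons %||% "ATG"))
  stats::setNames(codes, vapply(codes, function(c) as.character(c$table_id), character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Translate a nucleotide sequence
#'
#' Codons are read left to right; a trailing 1-2 nt remainder is ignored.
#' Any codon containing N (or other non-ACGT characters) translates to X.
#'
#' @param sequence DNA string, length >= 3.
#' @param code a [genetic_code()].
#' @param stop_policy `"truncate_at_stop"` stops at the first stop codon
#'   (stop symbol not included); `"read_through_marked"` translates the
#'   whole frame with stops rendered as `*`.
#' @return amino-acid string.
#' @export
translate_seq <- function(sequence, code = genetic_code(1L),
                          stop_policy = c("truncate_at_stop", "read_through_marked")) {
  stop_policy <- match.arg(stop_policy)
  if (length(sequence) != 1 || !nzchar(sequence)) stop("empty sequence")
  n <- nchar(sequence)
  if (n < 3) stop("sequence shorter than one codon")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(sequence, starts, starts + 2L)
  aa <- unname(code$codon_map[codons])
  aa[is.na(aa)] <- "X"
  if (stop_policy == "truncate_at_stop") {
    hit <- which(aa == "*")
    if (length(hit)) aa <- aa[seq_len(hit[1] - 1L)]
  }
  paste(aa, collapse = "")
}

empty_orf_tbl <- function() {
  tibble::tibble(contig_id = character(), start = integer(), end = integer(),
                 strand = character(), frame = integer(), code_table = integer(),
                 completeness = character(), length_aa = integer(), protein = character())
}

ORF_COMPLETENESS <- c("complete", "5prime_partial", "3prime_partial", "internal")

#' Six-frame ORF discovery under a genetic code
#'
#' Scans all six reading frames.  A complete ORF runs from a start codon to
#' the next in-frame stop (the stop codon is included in the interval but
#' not in the protein or `length_aa`).  ORFs open at a contig edge are
#' reported as `5prime_partial` (edge to first in-frame stop),
#' `3prime_partial` (start codon to edge, no stop) or `internal` (a frame
#' with no stop at all).  Nested starts sharing a stop are collapsed to the
#' longest ORF by default.  Coordinates are 0-based half-open on the
#' forward strand; `frame` is the offset (0-2) on the ORF's own strand.
#'
#' @param x contig tibble or named character vector of sequences.
#' @param code a [genetic_code()].
#' @param min_len_aa minimum protein length in amino acids, stop excluded
#'   (the `-m 100` convention of common ORF callers).
#' @param strands strands to scan.
#' @param completeness completeness classes to report.
#' @param require_start if `FALSE`, a "complete" ORF is taken from the
#'   position after the previous in-frame stop regardless of start codon
#'   (longest-ORF behaviour of assembly-annotation tools).
#' @param start_codons override the code's start-codon set.
#' @param collapse_nested keep only the longest ORF per (strand, frame,
#'   stop codon).
#' @return tibble of ORF records sorted by contig, position, strand.
#' @export
find_orfs <- function(x, code = genetic_code(1L), min_len_aa = 100L,
                      strands = c("+", "-"),
                      completeness = ORF_COMPLETENESS,
                      require_start = TRUE,
                      start_codons = NULL,
                      collapse_nested = TRUE) {
  contigs <- as_contig_tbl(x)
  stopifnot(min_len_aa >= 1L)
  completeness <- match.arg(completeness, ORF_COMPLETENESS, several.ok = TRUE)
  start_codons <- start_codons %||% code$start_codons
  res <- lapply(seq_len(nrow(contigs)), function(i)
    orfs_one_contig(contigs$id[i], contigs$sequence[i], code,
                    as.integer(min_len_aa), strands, completeness,
                    require_start, start_codons, collapse_nested))
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) return(empty_orf_tbl())
  dplyr::arrange(out, .data$contig_id, .data$start, .data$end, .data$strand)
}

orfs_one_contig <- function(id, seq, code, min_len_aa, strands, completeness,
                            require_start, start_codons, collapse_nested) {
  L <- nchar(seq)
  # accumulate plain vectors; one tibble is built at the end (this function
  # sits on the generator's rejection-sampling hot path)
  a_start <- integer(0); a_end <- integer(0); a_strand <- character(0)
  a_frame <- integer(0); a_compl <- character(0); a_len <- integer(0)
  a_prot <- character(0)
  for (strand in strands) {
    s <- if (strand == "+") seq else reverse_complement(seq)
    for (f in 0:2) {
      K <- (L - f) %/% 3L
      if (K < 1L) next
      pos1 <- f + 3L * (seq_len(K) - 1L) + 1L       # 1-based nt start of codon k
      codons <- substring(s, pos1, pos1 + 2L)
      aa <- unname(code$codon_map[codons])
      aa[is.na(aa)] <- "X"
      stop_k <- which(aa == "*")
      start_k <- which(codons %in% start_codons)

      emit <- function(k_from, k_to, compl, with_stop) {
        # codons k_from..k_to translated; with_stop: stop codon at k_to+1
        len <- k_to - k_from + 1L
        if (len < min_len_aa) return(invisible())
        start_local <- f + 3L * (k_from - 1L)
        end_local <- f + 3L * (if (with_stop) k_to + 1L else k_to)
        if (strand == "+") {
          st <- start_local; en <- end_local
        } else {
          st <- L - end_local; en <- L - start_local
        }
        n <- length(a_start) + 1L
        a_start[n] <<- st; a_end[n] <<- en; a_strand[n] <<- strand
        a_frame[n] <<- f; a_compl[n] <<- compl; a_len[n] <<- len
        a_prot[n] <<- paste(aa[k_from:k_to], collapse = "")
        invisible()
      }

      first_complete_at_1 <- FALSE
      prev <- 0L
      for (stp in stop_k) {
        ks <- if (require_start) start_k[start_k > prev & start_k < stp]
              else if (prev + 1L < stp) prev + 1L else integer(0)
        if (length(ks)) {
          if (collapse_nested) ks <- min(ks)
          for (k in ks) {
            emit(k, stp - 1L, "complete", TRUE)
            if (stp == stop_k[1] && k == 1L) first_complete_at_1 <- TRUE
          }
        }
        prev <- stp
      }
      if (length(stop_k)) {
        # 5' partial: frame edge to first stop, unless identical in span to
        # the complete ORF starting at codon 1
        st1 <- stop_k[1]
        if (!first_complete_at_1 && st1 > 1L)
          emit(1L, st1 - 1L, "5prime_partial", TRUE)
      }
      last_stop <- if (length(stop_k)) stop_k[length(stop_k)] else 0L
      ks <- start_k[start_k > last_stop]
      if (length(ks)) {
        if (collapse_nested) ks <- min(ks)
        for (k in ks) emit(k, K, "3prime_partial", FALSE)
      }
      if (!length(stop_k)) emit(1L, K, "internal", FALSE)
    }
  }
  if (!length(a_start)) return(empty_orf_tbl())
  out <- tibble::tibble(contig_id = id, start = a_start, end = a_end,
                        strand = a_strand, frame = a_frame,
                        code_table = code$table_id, completeness = a_compl,
                        length_aa = a_len, protein = a_prot)
  out[out$completeness %in% completeness, , drop = FALSE]
}

#' Write ORFs as GFF3 plus protein FASTA
#'
#' @param orfs tibble from [find_orfs()].
#' @param gff_path,faa_path output files (either may be NULL to skip).
#' @return invisibly, the ORF tibble.
#' @export
write_orfs <- function(orfs, gff_path = NULL, faa_path = NULL) {
  if (!is.null(gff_path)) {
    feat <- orfs[, c("contig_id", "start", "end", "strand", "code_table",
                     "completeness", "frame", "length_aa")]
    write_gff3(feat, gff_path, type = "CDS")
  }
  if (!is.null(faa_path)) {
    ids <- sprintf("%s|t%d|%s|%d-%d(%s)", orfs$contig_id, orfs$code_table,
                   orfs$completeness, orfs$start, orfs$end, orfs$strand)
    set <- Biostrings::AAStringSet(orfs$protein)
    names(set) <- ids
    Biostrings::writeXStringSet(set, faa_path)
  }
  invisible(orfs)
}
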