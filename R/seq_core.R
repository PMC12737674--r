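# Sequence model shared by all stages.
#
# Contigs are plain tibbles (id, sequence, description, length) holding an
# uppercase DNA alphabet over {A,C,G,T,N}; RNA input (U) is normalised to T
# on read and only rendered back as U in terminal-motif reports.  All
# internal coordinates are 0-based half-open; minus-strand features store
# forward-strand coordinates.  Conversion to 1-based inclusive happens only
# at GFF3 output.

IUPAC_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalise a nucleotide sequence
#'
#' Uppercases, converts U to T, maps IUPAC ambiguity letters to N and
#' rejects anything outside the IUPAC nucleotide alphabet.
#'
#' @param x character vector of sequences.
#' @param context label used in error messages (e.g. a record id).
#' @return character vector over {A,C,G,T,N}.
#' @export
normalize_sequence <- function(x, context = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- stringi::stri_detect_regex(x, "[^ACGTNRYSWKMBDHV]")
  if (any(bad)) {
    ch <- stringi::stri_extract_first_regex(x[bad][1], "[^ACGTNRYSWKMBDHV]")
    stop(sprintf("invalid character '%s' in %s", ch, context[min(which(bad), length(context))]))
  }
  chartr(paste(IUPAC_AMBIGUITY, collapse = ""),
         strrep("N", length(IUPAC_AMBIGUITY)), x)
}

new_contig_tbl <- function(id, sequence, description = "") {
  if (any(grepl("\\s", id))) stop("contig id contains whitespace: ", id[grepl("\\s", id)][1])
  if (anyDuplicated(id)) stop("duplicate contig id: ", id[duplicated(id)][1])
  if (any(!nzchar(sequence))) stop("empty sequence for contig: ", id[!nzchar(sequence)][1])
  tibble::tibble(id = as.character(id),
                 sequence = as.character(sequence),
                 description = as.character(description),
                 length = nchar(sequence))
}

# Accept either a contig tibble or a named character vector of sequences.
as_contig_tbl <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    return(new_contig_tbl(x$id, x$sequence,
                          if ("description" %in% names(x)) x$description else ""))
  }
  if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("sequences must be named or supplied as a contig tibble")
    return(new_contig_tbl(names(x), unname(x)))
  }
  stop("cannot interpret object of class ", class(x)[1], " as contigs")
}

#' Read a FASTA file into a contig tibble
#'
#' One row per record, file order preserved.  Sequences are normalised
#' (uppercase, U to T, IUPAC ambiguity letters to N); invalid characters,
#' empty records and duplicate ids are errors.  The id is the first
#' whitespace-delimited token of the header; the remainder becomes the
#' description.
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return tibble with columns id, sequence, description, length.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) stop("empty sequence for record '", ids[empty][1], "' in ", path)
  seqs <- normalize_sequence(seqs, context = ids)
  new_contig_tbl(ids, seqs, desc)
}

#' Write contigs to FASTA
#'
#' @param contigs contig tibble or named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  contigs <- as_contig_tbl(contigs)
  set <- Biostrings::DNAStringSet(contigs$sequence)
  names(set) <- ifelse(nzchar(contigs$description),
                       paste(contigs$id, contigs$description),
                       contigs$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed; N maps to N.  Vectorised.
#'
#' @param sequence character vector over {A,C,G,T,N}.
#' @return reverse-complemented sequences.
#' @export
reverse_complement <- function(sequence) {
  if (any(stringi::stri_detect_regex(sequence, "[^ACGTN]")))
    stop("reverse_complement: sequence contains characters outside {A,C,G,T,N}")
  stringi::stri_reverse(chartr("ACGT", "TGCA", sequence))
}

#' Write located features as GFF3
#'
#' Converts the package's 0-based half-open intervals to the 1-based
#' inclusive coordinates of the GFF3 spec.
#'
#' @param features tibble with contig_id, start, end, strand and optional
#'   type/attribute columns (anything beyond the fixed columns is folded
#'   into column 9 as `key=value`).
#' @param path output file.
#' @param source value for GFF column 2.
#' @param type feature type for column 3 when no `type` column is present.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(features, path, source = "viromine", type = "CDS") {
  stopifnot(all(c("contig_id", "start", "end", "strand") %in% names(features)))
  fixed <- c("contig_id", "start", "end", "strand", "type")
  extra <- setdiff(names(features), c(fixed, "protein", "sequence"))
  attrs <- vapply(seq_len(nrow(features)), function(i) {
    kv <- vapply(extra, function(k) paste0(k, "=", features[[k]][i]), character(1))
    paste(c(sprintf("ID=%s.%d", features$contig_id[i], i), kv), collapse = ";")
  }, character(1))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\t%s",
                   features$contig_id, source,
                   if ("type" %in% names(features)) features$type else rep(type, nrow(features)),
                   features$start + 1L, features$end, features$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
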