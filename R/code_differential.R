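# Coding-system differential: the retroplasmid/mitovirus signature.
#
# A contig is called mitochondrially coded when long complete ORFs exist
# only under the mitochondrial table.  Because table 4's stop set is a
# subset of table 1's, every table-1 ORF reappears under table 4 at the
# same coordinates; only table-4 ORFs *not* reproduced under table 1 count
# as mitochondrion-specific evidence, otherwise every nuclear transcript
# would trivially qualify.

CODING_CALLS <- c("nuclear_coding", "mitochondrial_coding", "dual_coding", "noncoding")

#' Classify a contig's coding system by codon-table differential
#'
#' Counts qualifying ORFs (complete, `>= min_len_aa`) under the nuclear and
#' mitochondrial tables and maps the counts to a call:
#' none/none -> `noncoding`; nuclear ORFs with no mito-specific extras ->
#' `nuclear_coding`; mito-specific ORFs only -> `mitochondrial_coding`;
#' both -> `dual_coding`.  A table-4 ORF with the same span and strand as a
#' table-1 ORF is not mito-specific.
#'
#' @param x a single contig (one-row tibble or named length-1 character).
#' @param min_len_aa qualifying length threshold (aa, stop excluded).
#' @param nuclear_table,mito_table NCBI table ids (the mitochondrial
#'   default 4 is what the "Mitochondrial-Protozoan" setting of common ORF
#'   callers selects).
#' @param require_complete count only complete ORFs (start + in-frame stop).
#' @param start_codons override the start-codon set for both tables.
#' @param orfs_nuclear,orfs_mito optional precomputed [find_orfs()] output
#'   for this contig (any completeness; filtered here), to avoid rescanning.
#' @return list of class `coding_system_call`: contig_id, call,
#'   n_orfs_table1, n_orfs_table4, n_mito_specific, single_orf,
#'   longest_aa_table1, longest_aa_table4.
#' @export
classify_coding_system <- function(x, min_len_aa = 100L,
                                   nuclear_table = 1L, mito_table = 4L,
                                   require_complete = TRUE,
                                   start_codons = "ATG",
                                   orfs_nuclear = NULL, orfs_mito = NULL) {
  contig <- as_contig_tbl(x)
  stopifnot(nrow(contig) == 1)
  compl <- if (require_complete) "complete" else ORF_COMPLETENESS
  if (is.null(orfs_nuclear))
    orfs_nuclear <- find_orfs(contig, genetic_code(nuclear_table, start_codons),
                              min_len_aa = min_len_aa, completeness = compl)
  if (is.null(orfs_mito))
    orfs_mito <- find_orfs(contig, genetic_code(mito_table, start_codons),
                           min_len_aa = min_len_aa, completeness = compl)
  qual <- function(o) o[o$contig_id == contig$id & o$completeness %in% compl &
                          o$length_aa >= min_len_aa, , drop = FALSE]
  o1 <- qual(orfs_nuclear); o4 <- qual(orfs_mito)
  span1 <- paste(o1$start, o1$end, o1$strand)
  mito_specific <- o4[!(paste(o4$start, o4$end, o4$strand) %in% span1), , drop = FALSE]
  n1 <- nrow(o1); n4 <- nrow(o4); nspec <- nrow(mito_specific)
  call <- if (n1 == 0 && nspec == 0) "noncoding"
          else if (n1 >= 1 && nspec == 0) "nuclear_coding"
          else if (n1 == 0 && nspec >= 1) "mitochondrial_coding"
          else "dual_coding"
  single <- switch(call,
                   nuclear_coding = n1 == 1L,
                   mitochondrial_coding = n4 == 1L,
                   NA)
  structure(list(contig_id = contig$id, call = call,
                 n_orfs_table1 = n1, n_orfs_table4 = n4,
                 n_mito_specific = nspec, single_orf = single,
                 longest_aa_table1 = if (n1) max(o1$length_aa) else 0L,
                 longest_aa_table4 = if (n4) max(o4$length_aa) else 0L,
                 mito_orfs = mito_specific, nuclear_orfs = o1),
            class = "coding_system_call")
}

#' @export
print.coding_system_call <- function(x, ...) {
  cat(sprintf("<coding_system_call> %s: %s (table1 ORFs %d, table4 ORFs %d, mito-specific %d, single_orf %s)\n",
              x$contig_id, x$call, x$n_orfs_table1, x$n_orfs_table4,
              x$n_mito_specific, format(x$single_orf)))
  invisible(x)
}

#' Tabulate coding-system calls
#' @param calls list of `coding_system_call` objects.
#' @return one row per contig.
#' @export
coding_calls_tbl <- function(calls) {
  dplyr::bind_rows(lapply(calls, function(c)
    tibble::tibble(contig_id = c$contig_id, call = c$call,
                   n_orfs_table1 = c$n_orfs_table1, n_orfs_table4 = c$n_orfs_table4,
                   n_mito_specific = c$n_mito_specific,
                   single_orf = c$single_orf,
                   longest_aa_table1 = c$longest_aa_table1,
                   longest_aa_table4 = c$longest_aa_table4)))
}
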