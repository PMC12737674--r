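# Conserved 5'/3' terminal motifs shared by the segments of a
# multi-segment virus.  Partitivirus genome segments carry short strictly
# conserved termini; the consensus here is per-column majority over the
# segments, accepted while every segment stays within the substitution
# budget, and capped so identical inputs do not yield a degenerate
# whole-sequence "consensus".

#' Conserved terminal consensus of a segment set
#'
#' `five_prime` is the longest prefix (min_len <= length <= max_len) whose
#' per-column majority consensus every segment matches with at most
#' `max_mismatch` substitutions; `three_prime` is the analogous suffix.
#' At `max_mismatch = 0` this is exactly the longest common prefix/suffix.
#' The result is independent of segment order and rendered in the RNA
#' alphabet (U for T), matching how segmented RNA virus termini are
#' reported; internal storage remains DNA.
#'
#' @param segments at least 2 segments: contig tibble or named character vector.
#' @param max_mismatch substitution budget per segment (default 0, strict).
#' @param min_len shortest motif worth reporting; below it the consensus is
#'   the empty string.
#' @param max_len length cap.
#' @param virus_id identifier carried into the result.
#' @return list of class `terminal_consensus`: virus_id, five_prime,
#'   three_prime (RNA alphabet), n_segments, max_mismatch_used.
#' @export
conserved_termini <- function(segments, max_mismatch = 0L, min_len = 3L,
                              max_len = 30L, virus_id = "virus") {
  segs <- as_contig_tbl(segments)
  if (nrow(segs) < 2) stop("conserved_termini: need at least 2 segments")
  cap <- min(max_len, min(segs$length))
  five <- consensus_end(segs$sequence, cap, min_len, max_mismatch, from_start = TRUE)
  three <- consensus_end(segs$sequence, cap, min_len, max_mismatch, from_start = FALSE)
  structure(list(virus_id = virus_id,
                 five_prime = chartr("T", "U", five),
                 three_prime = chartr("T", "U", three),
                 n_segments = nrow(segs),
                 max_mismatch_used = as.integer(max_mismatch)),
            class = "terminal_consensus")
}

consensus_end <- function(seqs, cap, min_len, max_mismatch, from_start) {
  if (cap < min_len) return("")
  ends <- vapply(seqs, function(s) {
    x <- if (from_start) substr(s, 1L, cap)
         else substr(s, nchar(s) - cap + 1L, nchar(s))
    if (!from_start) x <- stringi::stri_reverse(x)
    x
  }, character(1))
  mat <- do.call(rbind, strsplit(ends, ""))
  # per-column majority, alphabetical tie-break for determinism
  cons <- apply(mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[tab == max(tab)][1]
  })
  mism <- t(apply(mat, 1, function(row) cumsum(row != cons)))
  ok <- apply(mism <= max_mismatch, 2, all)
  best <- if (any(ok)) max(which(ok)) else 0L
  if (best < min_len) return("")
  out <- paste(cons[seq_len(best)], collapse = "")
  if (from_start) out else stringi::stri_reverse(out)
}

#' @export
print.terminal_consensus <- function(x, ...) {
  cat(sprintf("<terminal_consensus> %s (%d segments): 5' %s / 3' %s\n",
              x$virus_id, x$n_segments,
              ifelse(nzchar(x$five_prime), x$five_prime, "-"),
              ifelse(nzchar(x$three_prime), x$three_prime, "-")))
  invisible(x)
}

#' Terminal consensus for every declared segment group
#'
#' @param contigs contig tibble.
#' @param segment_groups tibble with columns virus_id, contig_id.
#' @param ... passed to [conserved_termini()].
#' @return tibble: virus_id, five_prime, three_prime, n_segments.
#' @export
termini_by_group <- function(contigs, segment_groups, ...) {
  contigs <- as_contig_tbl(contigs)
  groups <- split(segment_groups$contig_id, segment_groups$virus_id)
  rows <- lapply(names(groups), function(v) {
    segs <- contigs[contigs$id %in% groups[[v]], ]
    tc <- conserved_termini(segs, virus_id = v, ...)
    tibble::tibble(virus_id = v, five_prime = tc$five_prime,
                   three_prime = tc$three_prime, n_segments = tc$n_segments)
  })
  dplyr::bind_rows(rows)
}
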