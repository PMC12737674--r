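# Redundancy removal at identity/coverage thresholds.
#
# Near-identical sequences (nucleotide or protein) are collapsed with a
# CD-HIT-style greedy scheme: sort by length descending, each sequence
# joins the first existing representative it matches at >= min_identity
# and >= min_coverage, else founds a new cluster.  Coverage is computed on
# the shorter sequence so that fragments of a longer element are treated
# as redundant with it.

#' Pairwise alignment statistics
#'
#' Affine-gap dynamic-programming alignment (match +1, mismatch -1, gap
#' open -2, gap extend -1 by default; a gap of length k scores
#' `gap_open + k * gap_extend`).  `global_overlap` (dovetail) leaves
#' terminal overhangs unpenalised; `local` is Smith-Waterman.  Identity is
#' matches over aligned columns excluding terminal overhangs; coverage is
#' the aligned span on the shorter sequence over the shorter length.
#' Co-optimal alignments are resolved by a fixed lexicographic rule
#' (score, matches, fewest columns, longest span) so results are
#' deterministic.
#'
#' @param seq_a,seq_b sequences (both nucleotide or both amino acid).
#' @param mode `"global_overlap"` or `"local"`.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param id_a,id_b optional sequence ids for the result.
#' @return tibble: id_a, id_b, identity, coverage, alignment_length, score.
#' @export
pairwise_stats <- function(seq_a, seq_b, mode = c("global_overlap", "local"),
                           match = 1, mismatch = -1, gap_open = -2, gap_extend = -1,
                           id_a = "a", id_b = "b") {
  mode <- match.arg(mode)
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  if (is_nt_alphabet(seq_a) != is_nt_alphabet(seq_b))
    stop("pairwise_stats: sequences use different alphabets")
  res <- align_pair_cpp(seq_a, seq_b, match, mismatch, gap_open, gap_extend,
                        if (mode == "local") "local" else "overlap")
  len_a <- nchar(seq_a); len_b <- nchar(seq_b)
  shorter <- min(len_a, len_b)
  if (!res$valid || res$columns == 0) {
    return(tibble::tibble(id_a = id_a, id_b = id_b, identity = 0,
                          coverage = 0, alignment_length = 0L, score = 0))
  }
  span_short <- if (len_a <= len_b) res$a_end - res$a_start + 1L
                else res$b_end - res$b_start + 1L
  tibble::tibble(id_a = id_a, id_b = id_b,
                 identity = 100 * res$matches / res$columns,
                 coverage = 100 * span_short / shorter,
                 alignment_length = as.integer(res$columns),
                 score = res$score)
}

is_nt_alphabet <- function(x) {
  !stringi::stri_detect_regex(toupper(x), "[^ACGTUN]")
}

#' Greedy redundancy clustering
#'
#' Sequences are sorted by length descending (ties broken by id); each
#' sequence joins the earliest-founded representative it matches at both
#' thresholds, otherwise it becomes a new representative.
#'
#' @param sequences named character vector (nt or aa) or contig tibble.
#' @param min_identity,min_coverage percent thresholds (defaults 95/95).
#' @param mode,match,mismatch,gap_open,gap_extend alignment parameters
#'   passed to [pairwise_stats()].
#' @return list of class `cluster_result`: `representatives` (ordered ids),
#'   `membership` tibble (member_id, representative_id, identity, coverage).
#' @export
greedy_cluster <- function(sequences, min_identity = 95, min_coverage = 95,
                           mode = "global_overlap",
                           match = 1, mismatch = -1, gap_open = -2, gap_extend = -1) {
  if (is.data.frame(sequences))
    sequences <- stats::setNames(sequences$sequence, sequences$id)
  stopifnot(length(sequences) >= 1, !is.null(names(sequences)))
  ord <- order(-nchar(sequences), names(sequences), method = "radix")
  sequences <- sequences[ord]
  reps <- character(0)
  member <- character(length(sequences))
  ident <- cover <- numeric(length(sequences))
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    assigned <- FALSE
    for (r in reps) {
      st <- pairwise_stats(sequences[[i]], sequences[[r]], mode = mode,
                           match = match, mismatch = mismatch,
                           gap_open = gap_open, gap_extend = gap_extend,
                           id_a = id, id_b = r)
      if (st$identity >= min_identity && st$coverage >= min_coverage) {
        member[i] <- r; ident[i] <- st$identity; cover[i] <- st$coverage
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, id)
      member[i] <- id; ident[i] <- 100; cover[i] <- 100
    }
  }
  structure(list(representatives = reps,
                 membership = tibble::tibble(member_id = names(sequences),
                                             representative_id = member,
                                             identity = ident, coverage = cover)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d sequences in %d clusters\n",
              nrow(x$membership), length(x$representatives)))
  invisible(x)
}

#' Write cluster representatives and membership
#' @param clusters a `cluster_result`.
#' @param sequences the clustered sequences (named character vector).
#' @param fasta_path,tsv_path output files (NULL to skip).
#' @export
write_clusters <- function(clusters, sequences, fasta_path = NULL, tsv_path = NULL) {
  if (!is.null(fasta_path)) {
    set <- Biostrings::BStringSet(sequences[clusters$representatives])
    names(set) <- clusters$representatives
    Biostrings::writeXStringSet(set, fasta_path)
  }
  if (!is.null(tsv_path))
    readr::write_tsv(clusters$membership, tsv_path)
  invisible(clusters)
}
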