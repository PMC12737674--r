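# Screening funnel separating virus candidates, follow-up contigs and
# host-like contigs from annotated assembly output.
#
# The pipeline consumes similarity-search hit tables (DIAMOND/BLAST
# outfmt-6 dialects) rather than running the search engines; the column
# layout is declared so real outputs drop in unchanged.

HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity", "alignment_length",
                 "mismatches", "gap_opens", "query_start", "query_end",
                 "subject_start", "subject_end", "evalue", "bitscore",
                 "query_coverage", "subject_title", "subject_organism")

OUTFMT6_12 <- HIT_COLUMNS[1:12]

empty_hit_tbl <- function() {
  tibble::tibble(query_id = character(), subject_id = character(),
                 percent_identity = numeric(), alignment_length = integer(),
                 mismatches = integer(), gap_opens = integer(),
                 query_start = integer(), query_end = integer(),
                 subject_start = integer(), subject_end = integer(),
                 evalue = numeric(), bitscore = numeric(),
                 query_coverage = numeric(), subject_title = character(),
                 subject_organism = character())
}

#' Read a tabular similarity-search hit table
#'
#' @param path TSV file with no header, one hit per row.
#' @param dialect `"outfmt6"` (the standard 12 columns: qseqid sseqid pident
#'   length mismatch gapopen qstart qend sstart send evalue bitscore),
#'   `"outfmt6_extended"` (the 12 plus qcovs, stitle, sscinames), or a
#'   character vector naming each column in file order using the internal
#'   names `r paste(HIT_COLUMNS, collapse=", ")` (unused columns as `"."`).
#' @return hit tibble; optional columns missing from the dialect are filled
#'   with `"unknown"` (text) or `NA` (query_coverage).
#' @export
read_hit_table <- function(path, dialect = "outfmt6") {
  cols <- hit_dialect_columns(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hit_tbl())
  widths <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(widths != length(cols))
  if (length(bad))
    stop(sprintf("hit table '%s': row %d has %d columns, dialect declares %d",
                 path, bad[1], widths[bad[1]], length(cols)))
  raw <- suppressWarnings(
    readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                    progress = FALSE, na = character()))
  if (nrow(raw) == 0) return(empty_hit_tbl())
  names(raw) <- ifelse(cols == ".", paste0(".drop", seq_along(cols)), cols)
  raw <- raw[, cols[cols != "."], drop = FALSE]
  hits_from_raw(raw, path)
}

hit_dialect_columns <- function(dialect) {
  if (identical(dialect, "outfmt6")) return(OUTFMT6_12)
  if (identical(dialect, "outfmt6_extended"))
    return(c(OUTFMT6_12, "query_coverage", "subject_title", "subject_organism"))
  if (is.character(dialect) && length(dialect) > 1) {
    unknown <- setdiff(dialect, c(HIT_COLUMNS, "."))
    if (length(unknown)) stop("unknown hit-table column name: ", unknown[1])
    return(dialect)
  }
  stop("unknown hit-table dialect")
}

hits_from_raw <- function(raw, path) {
  num_cols <- c("percent_identity", "alignment_length", "mismatches", "gap_opens",
                "query_start", "query_end", "subject_start", "subject_end",
                "evalue", "bitscore", "query_coverage")
  for (cn in intersect(num_cols, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & nzchar(raw[[cn]]))
    if (length(bad))
      stop(sprintf("hit table '%s': non-numeric value '%s' in column %s, row %d",
                   path, raw[[cn]][bad[1]], cn, bad[1]))
    raw[[cn]] <- v
  }
  proto <- empty_hit_tbl()
  out <- tibble::as_tibble(lapply(stats::setNames(nm = names(proto)), function(cn) {
    if (cn %in% names(raw)) raw[[cn]] else rep(proto[[cn]][NA_integer_], nrow(raw))
  }))
  out$subject_title[is.na(out$subject_title)] <- "unknown"
  out$subject_organism[is.na(out$subject_organism)] <- "unknown"
  # normalise reversed query coordinates (minus-strand nucleotide hits)
  flip <- !is.na(out$query_start) & !is.na(out$query_end) & out$query_start > out$query_end
  if (any(flip)) {
    tmp <- out$query_start[flip]
    out$query_start[flip] <- out$query_end[flip]
    out$query_end[flip] <- tmp
  }
  if (any(!is.na(out$percent_identity) &
          (out$percent_identity < 0 | out$percent_identity > 100)))
    stop("percent identity outside [0,100] in ", path)
  if (any(!is.na(out$evalue) & out$evalue < 0)) stop("negative evalue in ", path)
  tibble::as_tibble(out)
}

#' Write a hit tibble as extended outfmt-6 TSV
#' @param hits hit tibble.
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c(OUTFMT6_12, "query_coverage", "subject_title", "subject_organism")
  readr::write_tsv(hits[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Best hit per query
#'
#' Lowest evalue wins; ties broken by highest bitscore, then highest
#' percent identity, then lexicographic subject id.
#'
#' @param hits hit tibble.
#' @return one-row-per-query hit tibble.
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::arrange(.data$query_id, .data$evalue, dplyr::desc(.data$bitscore),
                   dplyr::desc(.data$percent_identity), .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}

TRIAGE_CATEGORIES <- c("virus_candidate", "followup_no_orf",
                       "followup_unannotated_orf", "followup_divergent_hit",
                       "host_like")

#' Triage contigs into virus candidates, follow-up classes and host-like
#'
#' Category precedence, applied per contig:
#' 1. best-hit title contains "virus" (case-insensitive, also inside words
#'    such as "mitovirus") — `virus_candidate`;
#' 2. no qualifying ORF under any configured table — `followup_no_orf`;
#' 3. ORFs exist but the contig has no hit at all — `followup_unannotated_orf`;
#' 4. best-hit organism is neither the host nor a configured related
#'    species AND identity is below `identity_threshold` —
#'    `followup_divergent_hit`;
#' 5. otherwise `host_like`.
#'
#' @param contigs contig tibble.
#' @param orfs_by_code named list of [find_orfs()] tibbles (at least the
#'   nuclear and mitochondrial tables); only `complete` records count as
#'   qualifying ORFs.
#' @param best_hits output of [best_hit_per_query()] on the protein hits.
#' @param host_label organism label treated as host.
#' @param related_labels additional labels treated as host.
#' @param identity_threshold amino-acid identity (%) below which a
#'   non-host best hit marks the contig for follow-up.
#' @param min_len_aa qualifying-ORF length threshold (aa).
#' @param nucleotide_hits optional nucleotide-level hit tibble used to flag
#'   host sequence misassembled at contig ends (see
#'   [flag_end_contamination()]).
#' @param end_window_frac,host_identity_min end-contamination parameters.
#' @return tibble: contig_id, category, end_contamination, rationale.
#' @export
triage_contigs <- function(contigs, orfs_by_code, best_hits,
                           host_label = "Botrytis cinerea",
                           related_labels = character(),
                           identity_threshold = 90,
                           min_len_aa = 100L,
                           nucleotide_hits = NULL,
                           end_window_frac = 0.2,
                           host_identity_min = 90) {
  contigs <- as_contig_tbl(contigs)
  unknown <- setdiff(unique(best_hits$query_id), contigs$id)
  if (length(unknown))
    stop("hit table references contig absent from contig set: ", unknown[1])
  host_set <- c(host_label, related_labels)
  orf_ids <- unique(unlist(lapply(orfs_by_code, function(o)
    o$contig_id[o$completeness == "complete" & o$length_aa >= min_len_aa])))
  bh <- best_hits[match(contigs$id, best_hits$query_id), ]

  decide <- function(i) {
    hit <- bh[i, ]
    has_hit <- !is.na(hit$query_id)
    if (has_hit && grepl("virus", hit$subject_title, ignore.case = TRUE))
      return(c("virus_candidate",
               sprintf("best hit title contains 'virus': %s", hit$subject_title)))
    if (!(contigs$id[i] %in% orf_ids))
      return(c("followup_no_orf",
               sprintf("no complete ORF >= %d aa under any configured table", min_len_aa)))
    if (!has_hit)
      return(c("followup_unannotated_orf", "ORFs present but no database hit"))
    if (!(hit$subject_organism %in% host_set) &&
        hit$percent_identity < identity_threshold)
      return(c("followup_divergent_hit",
               sprintf("best hit %s (%s) at %.1f%% identity < %g%%",
                       hit$subject_id, hit$subject_organism,
                       hit$percent_identity, identity_threshold)))
    c("host_like", sprintf("best hit %s (%s) at %.1f%% identity",
                           hit$subject_id, hit$subject_organism, hit$percent_identity))
  }
  dec <- t(vapply(seq_len(nrow(contigs)), decide, character(2)))
  endflag <- vapply(seq_len(nrow(contigs)), function(i) {
    if (is.null(nucleotide_hits)) return("none")
    flag_end_contamination(contigs[i, ],
                           nucleotide_hits[nucleotide_hits$query_id == contigs$id[i], ],
                           host_label = host_label, related_labels = related_labels,
                           end_window_frac = end_window_frac,
                           host_identity_min = host_identity_min)$flag
  }, character(1))
  tibble::tibble(contig_id = contigs$id,
                 category = dec[, 1],
                 end_contamination = endflag,
                 rationale = dec[, 2])
}

#' Flag host sequence misassembled at contig ends
#'
#' A terminal end is flagged when a host-organism nucleotide hit with
#' identity >= `host_identity_min` covers at least half of that end's
#' window (window = `end_window_frac` x contig length) without extending
#' past the contig midpoint (a hit spanning the midpoint is whole-contig
#' host similarity, handled by triage instead).  Flagged intervals are
#' returned so a trim step can excise them.
#'
#' @param contig one-row contig tibble (or named length-1 character).
#' @param hits nucleotide-level hits of this contig (1-based inclusive
#'   query coordinates, as in BLAST tabular output).
#' @param host_label,related_labels organism labels treated as host.
#' @param end_window_frac fraction of the contig length forming each
#'   terminal window.
#' @param host_identity_min identity threshold for a host hit to count.
#' @return list: `flag` in none/left/right/both, `intervals` tibble of the
#'   flagged hit spans (1-based inclusive).
#' @export
flag_end_contamination <- function(contig, hits,
                                   host_label = "Botrytis cinerea",
                                   related_labels = character(),
                                   end_window_frac = 0.2,
                                   host_identity_min = 90) {
  contig <- as_contig_tbl(contig)
  stopifnot(nrow(contig) == 1)
  L <- contig$length
  w <- max(1L, floor(end_window_frac * L))
  mid <- L / 2
  host_set <- c(host_label, related_labels)
  flagged <- tibble::tibble(end = character(), query_start = integer(),
                            query_end = integer())
  if (!is.null(hits) && nrow(hits)) {
    hh <- hits[hits$subject_organism %in% host_set &
                 !is.na(hits$percent_identity) &
                 hits$percent_identity >= host_identity_min, ]
    for (i in seq_len(nrow(hh))) {
      qs <- hh$query_start[i]; qe <- hh$query_end[i]
      left_ov <- max(0, min(qe, w) - max(qs, 1) + 1)
      right_ov <- max(0, min(qe, L) - max(qs, L - w + 1) + 1)
      if (left_ov >= w / 2 && qe <= mid)
        flagged <- dplyr::bind_rows(flagged, tibble::tibble(
          end = "left", query_start = qs, query_end = qe))
      if (right_ov >= w / 2 && qs > mid)
        flagged <- dplyr::bind_rows(flagged, tibble::tibble(
          end = "right", query_start = qs, query_end = qe))
    }
  }
  ends <- unique(flagged$end)
  flag <- if (all(c("left", "right") %in% ends)) "both"
          else if ("left" %in% ends) "left"
          else if ("right" %in% ends) "right" else "none"
  list(flag = flag, intervals = flagged)
}
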