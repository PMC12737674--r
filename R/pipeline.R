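# End-to-end orchestration: read -> ORFs (nuclear + mitochondrial tables)
# -> triage -> end-contamination flags -> coding-system differential ->
# motif scan + element classification -> redundancy clustering of element
# proteins -> terminal consensus for declared segment groups -> report.
#
# Manual follow-up steps of a real virome study (remote profile searches,
# nucleotide-database confirmation, PCR validation) are represented as a
# needs_external_confirmation flag on the report rather than automated
# stages.  Deterministic for fixed inputs and config.

#' Default pipeline configuration
#'
#' Every threshold the pipeline applies, in one place: the qualifying-ORF
#' length (100 aa), the nuclear/mitochondrial table pair (1/4), the host
#' organism label and the 90% amino-acid identity bound separating
#' host-like from divergent best hits, the end-contamination window
#' (20% of contig length, half-window coverage, 90% identity), the 95/95
#' redundancy thresholds, and the terminal-consensus caps.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(min_len_aa = 100L,
       nuclear_table = 1L,
       mito_table = 4L,
       start_codons = "ATG",
       host_label = "Botrytis cinerea",
       related_host_labels = character(),
       identity_threshold = 90,
       end_window_frac = 0.2,
       host_identity_min = 90,
       cluster_min_identity = 95,
       cluster_min_coverage = 95,
       motifs = default_motifs(),
       termini = list(max_mismatch = 0L, min_len = 3L, max_len = 30L))
}

#' Run the full contig-triage and element-discovery pipeline
#'
#' @param contigs contig tibble, named character vector, or FASTA path.
#' @param protein_hits hit tibble or TSV path (dialect
#'   `"outfmt6_extended"` when a path is given).
#' @param nucleotide_hits optional nucleotide-level hits (tibble or path).
#' @param segment_groups optional tibble (virus_id, contig_id) declaring
#'   multi-segment viruses for terminal-consensus extraction.
#' @param config configuration list, see [default_config()].
#' @return list of class `pipeline_report`: `per_contig` (one row per
#'   input contig joining triage, coding call, element class, cluster
#'   membership), `summary` counts, `clusters`, `termini`, `orfs`,
#'   `config`, `version`.
#' @export
run_pipeline <- function(contigs, protein_hits, nucleotide_hits = NULL,
                         segment_groups = NULL, config = default_config()) {
  if (is.character(contigs) && length(contigs) == 1 && file.exists(contigs))
    contigs <- read_fasta(contigs)
  contigs <- as_contig_tbl(contigs)
  if (nrow(contigs) == 0) stop("no contigs")
  if (is.character(protein_hits))
    protein_hits <- read_hit_table(protein_hits, "outfmt6_extended")
  if (is.character(nucleotide_hits))
    nucleotide_hits <- read_hit_table(nucleotide_hits, "outfmt6_extended")

  code1 <- genetic_code(config$nuclear_table, config$start_codons)
  code4 <- genetic_code(config$mito_table, config$start_codons)
  orfs1 <- find_orfs(contigs, code1, min_len_aa = config$min_len_aa,
                     completeness = "complete")
  orfs4 <- find_orfs(contigs, code4, min_len_aa = config$min_len_aa,
                     completeness = "complete")

  best <- best_hit_per_query(protein_hits)
  triage <- triage_contigs(contigs, list(nuclear = orfs1, mito = orfs4), best,
                           host_label = config$host_label,
                           related_labels = config$related_host_labels,
                           identity_threshold = config$identity_threshold,
                           min_len_aa = config$min_len_aa,
                           nucleotide_hits = nucleotide_hits,
                           end_window_frac = config$end_window_frac,
                           host_identity_min = config$host_identity_min)

  calls <- lapply(seq_len(nrow(contigs)), function(i) {
    id <- contigs$id[i]
    classify_coding_system(contigs[i, ], min_len_aa = config$min_len_aa,
                           nuclear_table = config$nuclear_table,
                           mito_table = config$mito_table,
                           start_codons = config$start_codons,
                           orfs_nuclear = orfs1[orfs1$contig_id == id, ],
                           orfs_mito = orfs4[orfs4$contig_id == id, ])
  })
  names(calls) <- contigs$id

  elements <- lapply(calls, function(cc) {
    ann <- if (cc$call == "mitochondrial_coding" && nrow(cc$mito_orfs)) {
      dplyr::bind_rows(lapply(seq_len(nrow(cc$mito_orfs)), function(k)
        scan_motifs(cc$mito_orfs$protein[k], config$motifs,
                    protein_id = sprintf("%s.orf%d", cc$contig_id, k))))
    } else scan_motifs("", config$motifs)[0, ]
    classify_element(cc, ann, config$motifs)
  })

  # redundancy clustering over classified mitochondrial element proteins
  elem_prot <- character(0)
  for (cc in calls) {
    if (cc$call == "mitochondrial_coding" && nrow(cc$mito_orfs) > 0) {
      k <- which.max(cc$mito_orfs$length_aa)
      elem_prot[[cc$contig_id]] <- cc$mito_orfs$protein[k]
    }
  }
  clusters <- if (length(elem_prot) >= 1)
    greedy_cluster(elem_prot, min_identity = config$cluster_min_identity,
                   min_coverage = config$cluster_min_coverage)
  else NULL

  termini <- if (!is.null(segment_groups) && nrow(segment_groups))
    termini_by_group(contigs, segment_groups,
                     max_mismatch = config$termini$max_mismatch,
                     min_len = config$termini$min_len,
                     max_len = config$termini$max_len)
  else tibble::tibble(virus_id = character(), five_prime = character(),
                      three_prime = character(), n_segments = integer())

  call_tbl <- coding_calls_tbl(calls)
  elem_tbl <- tibble::tibble(
    contig_id = unname(vapply(elements, `[[`, character(1), "contig_id")),
    element_class = unname(vapply(elements, `[[`, character(1), "element_class")))
  memb <- if (!is.null(clusters)) clusters$membership else
    tibble::tibble(member_id = character(), representative_id = character())

  per_contig <- triage |>
    dplyr::left_join(call_tbl, by = "contig_id") |>
    dplyr::left_join(elem_tbl, by = "contig_id") |>
    dplyr::left_join(dplyr::select(memb, contig_id = "member_id",
                                   cluster_representative = "representative_id"),
                     by = "contig_id") |>
    dplyr::left_join(dplyr::select(segment_groups %||%
                                     tibble::tibble(virus_id = character(),
                                                    contig_id = character()),
                                   "contig_id", segment_group = "virus_id"),
                     by = "contig_id") |>
    dplyr::mutate(needs_external_confirmation =
                    .data$category %in% c("virus_candidate",
                                          "followup_divergent_hit",
                                          "followup_unannotated_orf"))
  stopifnot(nrow(per_contig) == nrow(contigs))

  summary <- list(
    n_contigs = nrow(contigs),
    by_category = as.list(table(per_contig$category)),
    by_element_class = as.list(table(per_contig$element_class)),
    n_clusters = if (!is.null(clusters)) length(clusters$representatives) else 0L)

  structure(list(per_contig = per_contig, summary = summary,
                 clusters = clusters, termini = termini,
                 orfs = list(nuclear = orfs1, mito = orfs4),
                 config = config,
                 version = as.character(utils::packageVersion("viromine"))),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d contigs\n", x$summary$n_contigs))
  cat("  categories:", paste(sprintf("%s=%d", names(x$summary$by_category),
                                     unlist(x$summary$by_category)), collapse = " "), "\n")
  if (length(x$summary$by_element_class))
    cat("  elements:  ", paste(sprintf("%s=%d", names(x$summary$by_element_class),
                                       unlist(x$summary$by_element_class)), collapse = " "), "\n")
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Emits the per-contig table (TSV), terminal consensi (TSV), cluster
#' membership (TSV) and a JSON summary including the config snapshot
#' (sufficient to re-run; no timestamps, so re-runs are byte-identical).
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$per_contig, file.path(dir, "per_contig.tsv"))
  readr::write_tsv(report$termini, file.path(dir, "termini.tsv"))
  if (!is.null(report$clusters))
    readr::write_tsv(report$clusters$membership, file.path(dir, "clusters.tsv"))
  jsonlite::write_json(list(summary = report$summary, config = report$config,
                            version = report$version),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' Map pipeline outcomes back to generator classes
#'
#' For a report produced from a [make_dataset()] dataset, derives the
#' predicted class of each contig from its triage category, coding call,
#' element class and end-contamination flag, and tabulates the confusion
#' matrix against the planted labels.
#'
#' @param report a `pipeline_report`.
#' @param labels the dataset's labels tibble (contig_id, class).
#' @return list: `predicted` tibble, `confusion` (truth x predicted
#'   table), `per_class_recovery` named vector (%), `accuracy` (%).
#' @export
evaluate_recovery <- function(report, labels) {
  pc <- report$per_contig
  predict_one <- function(i) {
    cat_ <- pc$category[i]
    call_ <- pc$call[i]
    elem <- pc$element_class[i]
    flag <- pc$end_contamination[i]
    if (cat_ == "virus_candidate") {
      if (identical(call_, "mitochondrial_coding")) "M" else "P"
    } else if (cat_ == "followup_divergent_hit") {
      if (identical(elem, "retroplasmid")) "R"
      else if (identical(elem, "group_II_intron")) "G2"
      else "other"
    } else if (cat_ == "followup_no_orf") {
      "N"
    } else if (cat_ == "host_like") {
      if (!identical(flag, "none")) "C" else "H"
    } else "other"
  }
  predicted <- tibble::tibble(contig_id = pc$contig_id,
                              predicted = vapply(seq_len(nrow(pc)), predict_one,
                                                 character(1)))
  joined <- dplyr::inner_join(labels, predicted, by = "contig_id")
  classes <- sort(unique(joined$class))
  confusion <- table(truth = joined$class,
                     predicted = factor(joined$predicted,
                                        levels = union(classes, unique(joined$predicted))))
  recovery <- vapply(classes, function(cl) {
    sub <- joined[joined$class == cl, ]
    100 * mean(sub$predicted == cl)
  }, numeric(1))
  list(predicted = predicted, confusion = confusion,
       per_class_recovery = recovery,
       accuracy = 100 * mean(joined$predicted == joined$class))
}
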