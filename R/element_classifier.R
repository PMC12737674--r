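# Domain-architecture classification of mitochondrially coded proteins.
#
# Motif definitions are configuration, not hard-coded biology: the default
# set ships a reverse-transcriptase core (the canonical YxDD box,
# generalised to [YF]-x-D-D), a type II intron maturase placeholder, an
# HNH endonuclease placeholder and the RdRP GDD triad.  Patterns use a
# PROSITE-like syntax; the synthetic generator plants exactly the
# configured patterns so the classification tests are self-consistent
# without claiming profile-HMM fidelity.

ELEMENT_CLASSES <- c("retroplasmid", "group_II_intron", "mitovirus_like",
                     "unknown_mito_element", "not_applicable")

#' Default motif configuration
#'
#' Each motif is a list with `name`, `pattern` (PROSITE-style: elements
#' separated by `-`; a fixed residue, a residue class `[XYZ]`, or a bounded
#' gap `x`, `x(n)`, `x(m,n)`), `min_score` (matches required for the motif
#' to count as present) and `realization` (an exemplar sequence matching
#' the pattern, used by the synthetic generator).
#'
#' @return list of motif definitions.
#' @export
default_motifs <- function() {
  list(
    list(name = "RVT_1", pattern = "[YF]-x-D-D", min_score = 1L,
         realization = "YADD"),
    list(name = "Intron_maturas2", pattern = "R-[LM]-x(1,3)-G-[WY]", min_score = 1L,
         realization = "RLAGW"),
    list(name = "AI2M_like_HNH", pattern = "H-x(2,3)-N-x(2,3)-H", min_score = 1L,
         realization = "HAANAAH"),
    list(name = "RdRP_core", pattern = "G-D-D", min_score = 1L,
         realization = "GDD")
  )
}

#' Load motif definitions from YAML
#' @param path YAML file: list of {name, pattern, min_score, realization}.
#' @return validated motif list (patterns compiled eagerly so malformed
#'   patterns fail at load time).
#' @export
load_motifs <- function(path) {
  motifs <- yaml::read_yaml(path)
  lapply(motifs, function(m) {
    stopifnot(!is.null(m$name), !is.null(m$pattern))
    compile_motif_pattern(m$pattern)  # errors on malformed patterns
    m$min_score <- as.integer(m$min_score %||% 1L)
    m
  })
}

#' Compile a PROSITE-style protein pattern to a regular expression
#'
#' @param pattern e.g. `"[YF]-x-D-D"` or `"H-x(2,3)-N-x(2,3)-H"`.
#' @return single regex string (perl-compatible).
#' @export
compile_motif_pattern <- function(pattern) {
  if (!nzchar(pattern)) stop("empty motif pattern")
  parts <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  rx <- vapply(parts, function(p) {
    if (grepl("^[A-Z]$", p) && p != "X") return(p)
    if (p == "x" || p == "X") return(".")
    if (grepl("^\\[[A-Z]+\\]$", p)) return(p)
    m <- regmatches(p, regexec("^x\\((\\d+)(?:,(\\d+))?\\)$", p))[[1]]
    if (length(m)) {
      lo <- as.integer(m[2])
      hi <- if (nzchar(m[3])) as.integer(m[3]) else lo
      if (hi < lo) stop("malformed gap bounds in motif element: ", p)
      return(sprintf(".{%d,%d}", lo, hi))
    }
    stop("malformed motif pattern element: ", p)
  }, character(1))
  paste(rx, collapse = "")
}

#' Scan a protein for configured motifs
#'
#' Reports all non-overlapping leftmost matches of each pattern
#' (deterministic left-to-right scan).
#'
#' @param protein amino-acid string.
#' @param motifs motif list (see [default_motifs()]).
#' @param protein_id identifier recorded with the annotations.
#' @return tibble: protein_id, motif_name, position (1-based aa offset),
#'   matched_span.
#' @export
scan_motifs <- function(protein, motifs = default_motifs(), protein_id = "protein") {
  stopifnot(is.character(protein), length(protein) == 1)
  out <- lapply(motifs, function(m) {
    rx <- compile_motif_pattern(m$pattern)
    hits <- gregexpr(rx, protein, perl = TRUE)[[1]]
    if (hits[1] == -1L) return(NULL)
    tibble::tibble(protein_id = protein_id, motif_name = m$name,
                   position = as.integer(hits),
                   matched_span = unlist(regmatches(protein, list(hits))))
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out))
    return(tibble::tibble(protein_id = character(), motif_name = character(),
                          position = integer(), matched_span = character()))
  out
}

#' Classify a mitochondrially coded element by domain architecture
#'
#' Precedence (total and deterministic):
#' reverse transcriptase plus maturase or HNH endonuclease evidence ->
#' `group_II_intron`; reverse transcriptase alone on a single-ORF element ->
#' `retroplasmid`; RdRP core -> `mitovirus_like`; anything else ->
#' `unknown_mito_element`.  Non-mitochondrial coding calls pass through as
#' `not_applicable`.
#'
#' @param coding_call a [classify_coding_system()] result.
#' @param annotations [scan_motifs()] tibble for the element's protein(s).
#' @param motifs motif list supplying the `min_score` thresholds.
#' @return list of class `element_call`: contig_id, element_class,
#'   evidence (the annotations), coding_call.
#' @export
classify_element <- function(coding_call, annotations, motifs = default_motifs()) {
  present <- function(name) {
    ms <- Filter(function(m) m$name == name, motifs)
    min_score <- if (length(ms)) ms[[1]]$min_score %||% 1L else 1L
    sum(annotations$motif_name == name) >= min_score
  }
  cls <- if (!identical(coding_call$call, "mitochondrial_coding")) {
    "not_applicable"
  } else if (present("RVT_1") && (present("Intron_maturas2") || present("AI2M_like_HNH"))) {
    "group_II_intron"
  } else if (present("RVT_1") && isTRUE(coding_call$single_orf)) {
    "retroplasmid"
  } else if (present("RdRP_core")) {
    "mitovirus_like"
  } else {
    "unknown_mito_element"
  }
  structure(list(contig_id = coding_call$contig_id, element_class = cls,
                 evidence = annotations, coding_call = coding_call),
            class = "element_call")
}

#' @export
print.element_call <- function(x, ...) {
  cat(sprintf("<element_call> %s: %s (%d motif annotations)\n",
              x$contig_id, x$element_class, nrow(x$evidence)))
  invisible(x)
}
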