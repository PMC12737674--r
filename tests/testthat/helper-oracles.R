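# Independent oracles used to validate the package's optimised
# implementations: a position-by-position ORF enumerator, a full-matrix
# alignment DP, and an exhaustive alignment enumerator for tiny inputs.

# ---- brute-force ORF enumerator --------------------------------------------
# Walks every frame and strand codon by codon, testing every start
# position explicitly; no shared code with find_orfs beyond the codon map.
orf_oracle <- function(id, seq, code, min_len_aa = 100L,
                       require_start = TRUE, collapse_nested = TRUE,
                       start_codons = code$start_codons) {
  rows <- list()
  L <- nchar(seq)
  add <- function(strand, f, start_local, end_local, compl, prot) {
    if (strand == "+") { st <- start_local; en <- end_local }
    else { st <- L - end_local; en <- L - start_local }
    rows[[length(rows) + 1L]] <<- data.frame(
      contig_id = id, start = st, end = en, strand = strand, frame = f,
      code_table = code$table_id, completeness = compl,
      length_aa = nchar(prot), protein = prot, stringsAsFactors = FALSE)
  }
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else viromine::reverse_complement(seq)
    for (f in 0:2) {
      if (f + 3L > L) next
      npos <- seq(f + 1L, L - 2L, by = 3L)
      aa <- vapply(npos, function(p) {
        a <- unname(code$codon_map[substr(s, p, p + 2L)])
        if (is.na(a)) "X" else a
      }, character(1))
      starts <- vapply(npos, function(p)
        substr(s, p, p + 2L) %in% start_codons, logical(1))
      stops <- which(aa == "*")
      prot_between <- function(k1, k2)
        if (k2 < k1) "" else paste(aa[k1:k2], collapse = "")
      emitted_first_complete <- FALSE
      prev <- 0L
      for (stp in stops) {
        cands <- which(starts)
        cands <- cands[cands > prev & cands < stp]
        if (!require_start)
          cands <- if (prev + 1L < stp) prev + 1L else integer(0)
        if (length(cands)) {
          use <- if (collapse_nested) min(cands) else cands
          for (k in use) {
            prot <- prot_between(k, stp - 1L)
            if (nchar(prot) >= min_len_aa)
              add(strand, f, f + 3L * (k - 1L), f + 3L * stp, "complete", prot)
            if (stp == stops[1] && k == 1L) emitted_first_complete <- TRUE
          }
        }
        prev <- stp
      }
      if (length(stops) && !emitted_first_complete && stops[1] > 1L) {
        prot <- prot_between(1L, stops[1] - 1L)
        if (nchar(prot) >= min_len_aa)
          add(strand, f, f, f + 3L * stops[1], "5prime_partial", prot)
      }
      last <- if (length(stops)) stops[length(stops)] else 0L
      cands <- which(starts)
      cands <- cands[cands > last]
      if (length(cands)) {
        use <- if (collapse_nested) min(cands) else cands
        for (k in use) {
          prot <- prot_between(k, length(npos))
          if (nchar(prot) >= min_len_aa)
            add(strand, f, f + 3L * (k - 1L), f + 3L * length(npos),
                "3prime_partial", prot)
        }
      }
      if (!length(stops)) {
        prot <- prot_between(1L, length(npos))
        if (nchar(prot) >= min_len_aa)
          add(strand, f, f, f + 3L * length(npos), "internal", prot)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out
}

orf_tbl_for_compare <- function(x) {
  if (is.null(x) || nrow(x) == 0) return(data.frame())
  x <- as.data.frame(x)[, c("contig_id", "start", "end", "strand", "frame",
                            "completeness", "length_aa", "protein")]
  x <- x[order(x$contig_id, x$start, x$end, x$strand, x$completeness), ,
         drop = FALSE]
  rownames(x) <- NULL
  x
}

# ---- full-matrix alignment DP oracle ---------------------------------------
# Same objective as the package aligner (score, then matches, then fewest
# columns, then longest span, origin as final tie-break) but written as an
# explicit full-matrix recursion over list-valued cells.
align_oracle_dp <- function(a, b, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1, mode = "overlap") {
  n <- nchar(a); m <- nchar(b)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  local <- mode == "local"
  invalid <- list(ok = FALSE)
  empty_grid <- function() {
    g <- vector("list", (n + 1L) * (m + 1L))
    for (k in seq_along(g)) g[[k]] <- invalid
    g
  }
  idx <- function(i, j) i * (m + 1L) + j + 1L   # (i, j) consumed counts
  M <- empty_grid(); X <- empty_grid(); Y <- empty_grid()
  better <- function(x, y) {
    if (!isTRUE(x$ok)) return(FALSE)
    if (!isTRUE(y$ok)) return(TRUE)
    if (x$s != y$s) return(x$s > y$s)
    if (x$mat != y$mat) return(x$mat > y$mat)
    if (x$col != y$col) return(x$col < y$col)
    if ((x$oi + x$oj) != (y$oi + y$oj)) return((x$oi + x$oj) < (y$oi + y$oj))
    if (x$oi != y$oi) return(x$oi < y$oi)
    x$oj < y$oj
  }
  best_end <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      start <- list(s = 0, mat = 0L, col = 0L, oi = i - 1L, oj = j - 1L,
                    ok = local || (i - 1L == 0L) || (j - 1L == 0L))
      if (!start$ok) start <- invalid
      pred <- invalid
      for (cnd in list(M[[idx(i - 1L, j - 1L)]], X[[idx(i - 1L, j - 1L)]],
                       Y[[idx(i - 1L, j - 1L)]], start))
        if (better(cnd, pred)) pred <- cnd
      if (isTRUE(pred$ok)) {
        eq <- A[i] == B[j]
        v <- list(s = pred$s + if (eq) match else mismatch,
                  mat = pred$mat + as.integer(eq), col = pred$col + 1L,
                  oi = pred$oi, oj = pred$oj, ok = TRUE)
        M[[idx(i, j)]] <- v
        edge <- (i == n) || (j == m)
        if ((local && v$s > 0) || (!local && edge)) {
          e <- c(v, list(ei = i, ej = j))
          if (is.null(best_end) || align_end_better(e, best_end)) best_end <- e
        }
      }
      open <- M[[idx(i - 1L, j)]]; ext <- X[[idx(i - 1L, j)]]
      if (isTRUE(open$ok)) open$s <- open$s + gap_open + gap_extend
      if (isTRUE(ext$ok)) ext$s <- ext$s + gap_extend
      vx <- if (better(open, ext)) open else ext
      if (isTRUE(vx$ok)) { vx$col <- vx$col + 1L; X[[idx(i, j)]] <- vx }
      open <- M[[idx(i, j - 1L)]]; ext <- Y[[idx(i, j - 1L)]]
      if (isTRUE(open$ok)) open$s <- open$s + gap_open + gap_extend
      if (isTRUE(ext$ok)) ext$s <- ext$s + gap_extend
      vy <- if (better(open, ext)) open else ext
      if (isTRUE(vy$ok)) { vy$col <- vy$col + 1L; Y[[idx(i, j)]] <- vy }
    }
  }
  if (is.null(best_end))
    return(list(valid = FALSE, score = 0, matches = 0L, columns = 0L))
  list(valid = TRUE, score = best_end$s, matches = best_end$mat,
       columns = best_end$col,
       a_start = best_end$oi + 1L, a_end = best_end$ei,
       b_start = best_end$oj + 1L, b_end = best_end$ej)
}

align_end_better <- function(x, y) {
  if (x$s != y$s) return(x$s > y$s)
  if (x$mat != y$mat) return(x$mat > y$mat)
  if (x$col != y$col) return(x$col < y$col)
  spx <- (x$ei - x$oi) + (x$ej - x$oj)
  spy <- (y$ei - y$oi) + (y$ej - y$oj)
  if (spx != spy) return(spx > spy)
  if (x$oi != y$oi) return(x$oi < y$oi)
  if (x$oj != y$oj) return(x$oj < y$oj)
  if (x$ei != y$ei) return(x$ei < y$ei)
  x$ej < y$ej
}

# ---- exhaustive alignment enumeration (tiny inputs) ------------------------
# Enumerates every dovetail alignment that starts and ends with an aligned
# pair (a gap in one sequence never directly follows a gap in the other),
# scoring a gap of length k as open + k*extend; returns the optimum of
# (score, matches, fewest columns).  Exponential; sequences <= 8 nt only.
align_enumerate <- function(a, b, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  n <- nchar(a); m <- nchar(b)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- NULL
  consider <- function(s, mat, col) {
    key <- c(s, mat, -col)
    if (is.null(best)) { best <<- key; return(invisible()) }
    for (d in seq_along(key)) {
      if (key[d] > best[d]) { best <<- key; return(invisible()) }
      if (key[d] < best[d]) return(invisible())
    }
  }
  recurse <- function(i, j, state, s, mat, col) {
    if (state == "M" && (i == n || j == m)) consider(s, mat, col)
    if (i < n && j < m) {
      eq <- A[i + 1] == B[j + 1]
      recurse(i + 1L, j + 1L, "M", s + if (eq) match else mismatch,
              mat + as.integer(eq), col + 1L)
    }
    if (i < n && state %in% c("M", "X"))
      recurse(i + 1L, j, "X",
              s + if (state == "X") gap_extend else gap_open + gap_extend,
              mat, col + 1L)
    if (j < m && state %in% c("M", "Y"))
      recurse(i, j + 1L, "Y",
              s + if (state == "Y") gap_extend else gap_open + gap_extend,
              mat, col + 1L)
  }
  for (oi in 0:(n - 1L)) recurse(oi, 0L, "S", 0, 0L, 0L)
  for (oj in seq_len(m - 1L)) recurse(0L, oj, "S", 0, 0L, 0L)
  if (is.null(best)) return(NULL)
  list(score = best[1], matches = best[2], columns = -best[3])
}

# shared fixture helpers ------------------------------------------------------

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                    collapse = "")
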