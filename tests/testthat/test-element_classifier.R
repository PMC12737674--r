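fake_call <- function(call = "mitochondrial_coding", single = TRUE, id = "c1") {
  structure(list(contig_id = id, call = call, single_orf = single),
            class = "coding_system_call")
}

ann_for <- function(...) {
  names <- c(character(0), ...)
  tibble::tibble(protein_id = rep("p", length(names)), motif_name = names,
                 position = seq_along(names), matched_span = names)
}

test_that("PROSITE-style patterns compile and malformed ones fail at load", {
  expect_equal(compile_motif_pattern("[YF]-x-D-D"), "[YF].DD")
  expect_equal(compile_motif_pattern("H-x(2,3)-N-x(2,3)-H"), "H.{2,3}N.{2,3}H")
  expect_equal(compile_motif_pattern("x(4)"), ".{4,4}")
  expect_error(compile_motif_pattern(""), "empty")
  expect_error(compile_motif_pattern("Y-x(4,2)-D"), "malformed")
  expect_error(compile_motif_pattern("Y-foo-D"), "malformed")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- name: bad", "  pattern: Y-x(,)-D"), f)
  expect_error(load_motifs(f), "malformed")
})

test_that("motif scanning finds planted sites at their offsets", {
  withr::local_seed(12)
  prot <- paste0(paste(sample(setdiff(viromine:::AA20, c("D", "Y", "F")), 40,
                              replace = TRUE), collapse = ""),
                 "YADD",
                 paste(sample(setdiff(viromine:::AA20, c("D", "Y", "F")), 30,
                              replace = TRUE), collapse = ""))
  ann <- scan_motifs(prot, default_motifs())
  rvt <- ann[ann$motif_name == "RVT_1", ]
  expect_equal(nrow(rvt), 1)
  expect_equal(rvt$position, 41L)
  expect_equal(rvt$matched_span, "YADD")
  expect_equal(nrow(scan_motifs(prot, list())), 0)
})

test_that("bounded gaps reject out-of-range spacings", {
  motif <- list(list(name = "gap", pattern = "A-x(2,4)-C", min_score = 1L))
  # hand-enumerated: gaps of 2..4 match, 1 and 5 do not
  expect_equal(nrow(scan_motifs("AGGC", motif)), 1)
  expect_equal(nrow(scan_motifs("AGGGGC", motif)), 1)
  expect_equal(nrow(scan_motifs("AGC", motif)), 0)
  expect_equal(nrow(scan_motifs("AGGGGGC", motif)), 0)
})

test_that("element classification precedence is total and deterministic", {
  cases <- list(
    list(ann = ann_for("RVT_1"), single = TRUE, want = "retroplasmid"),
    list(ann = ann_for("RVT_1", "Intron_maturas2", "AI2M_like_HNH"),
         single = TRUE, want = "group_II_intron"),
    list(ann = ann_for("RVT_1", "AI2M_like_HNH"), single = FALSE,
         want = "group_II_intron"),
    list(ann = ann_for("RVT_1"), single = FALSE, want = "unknown_mito_element"),
    list(ann = ann_for("RdRP_core"), single = TRUE, want = "mitovirus_like"),
    # group II intron evidence outranks the RdRP triad
    list(ann = ann_for("RVT_1", "Intron_maturas2", "RdRP_core"), single = TRUE,
         want = "group_II_intron"),
    list(ann = ann_for(), single = TRUE, want = "unknown_mito_element"))
  for (cs in cases) {
    got <- classify_element(fake_call(single = cs$single), cs$ann)
    expect_equal(got$element_class, cs$want)
  }
  expect_equal(classify_element(fake_call("nuclear_coding"),
                                ann_for("RVT_1"))$element_class,
               "not_applicable")
})

test_that("min_score demands repeated motif evidence when configured", {
  motifs <- default_motifs()
  motifs[[1]]$min_score <- 2L
  one_site <- ann_for("RVT_1")
  two_sites <- ann_for("RVT_1", "RVT_1")
  expect_equal(classify_element(fake_call(), one_site, motifs)$element_class,
               "unknown_mito_element")
  expect_equal(classify_element(fake_call(), two_sites, motifs)$element_class,
               "retroplasmid")
})

test_that("planted generator classes are recovered without confusion", {
  ds <- make_dataset(seed = 77, n_per_class = c(R = 4, M = 4, G2 = 4))
  got <- vapply(seq_len(nrow(ds$contigs)), function(i) {
    cc <- classify_coding_system(ds$contigs[i, ])
    ann <- dplyr::bind_rows(lapply(cc$mito_orfs$protein, scan_motifs))
    classify_element(cc, ann)$element_class
  }, character(1))
  lab <- ds$labels$class[match(ds$contigs$id, ds$labels$contig_id)]
  want <- c(R = "retroplasmid", M = "mitovirus_like", G2 = "group_II_intron")[lab]
  expect_equal(got, unname(want))
})
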