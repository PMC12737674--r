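test_that("codon tables carry the TGA stop/Trp difference", {
  t1 <- genetic_code(1)
  t4 <- genetic_code(4)
  expect_length(t1$codon_map, 64)
  expect_length(t4$codon_map, 64)
  expect_equal(unname(t1$codon_map[["TGA"]]), "*")
  expect_equal(unname(t4$codon_map[["TGA"]]), "W")
  expect_setequal(t1$stop_codons, c("TAA", "TAG", "TGA"))
  expect_setequal(t4$stop_codons, c("TAA", "TAG"))
  expect_true(all(t4$stop_codons %in% t1$stop_codons))
  expect_error(genetic_code(99), "unknown")
})

test_that("genetic codes load from a YAML registry file", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- table_id: 1", "- table_id: 4", "  start_codons: [ATG, GTG]"), f)
  codes <- load_genetic_codes(f)
  expect_named(codes, c("1", "4"))
  expect_equal(codes[["4"]]$start_codons, c("ATG", "GTG"))
})

test_that("translation respects table, stop policy and N codons", {
  expect_equal(translate_seq("ATGAAATGA", genetic_code(1)), "MK")
  expect_equal(translate_seq("ATGAAATGA", genetic_code(4)), "MKW")
  expect_equal(translate_seq("ATGNNA", genetic_code(1), "read_through_marked"), "MX")
  expect_equal(translate_seq("ATGAAATGAC", genetic_code(1), "read_through_marked"),
               "MK*")  # trailing nt ignored
  expect_error(translate_seq("", genetic_code(1)), "empty")
  expect_error(translate_seq("AT", genetic_code(1)), "codon")
})

test_that("an internal TGA forces a longer ORF under the mitochondrial code", {
  contig <- c(forced = paste0("ATG", strrep("GCA", 300), "TGA",
                              strrep("GCA", 300), "TAA"))
  o1 <- find_orfs(contig, genetic_code(1), completeness = "complete")
  o4 <- find_orfs(contig, genetic_code(4), completeness = "complete")
  expect_equal(max(o1$length_aa), 301L)
  expect_equal(max(o4$length_aa), 602L)
  # the table-1 ORF ends at the TGA, the table-4 ORF at the terminal TAA
  expect_equal(o1$end[which.max(o1$length_aa)], 3L + 900L + 3L)
  expect_equal(o4$end[which.max(o4$length_aa)], nchar(contig[[1]]))
})

test_that("contigs shorter than the ORF threshold yield nothing", {
  withr::local_seed(2)
  expect_equal(nrow(find_orfs(c(x = random_dna_str(50)), genetic_code(1),
                              min_len_aa = 100)), 0L)
})

test_that("find_orfs matches the brute-force enumerator on random contigs", {
  withr::local_seed(101)
  for (i in 1:30) {
    s <- random_dna_str(600)
    id <- sprintf("r%03d", i)
    for (tid in c(1, 4)) {
      code <- genetic_code(tid)
      got <- orf_tbl_for_compare(find_orfs(stats::setNames(s, id), code,
                                           min_len_aa = 30))
      want <- orf_tbl_for_compare(orf_oracle(id, s, code, min_len_aa = 30))
      expect_equal(got, want, info = sprintf("contig %s table %d", id, tid))
    }
  }
})

test_that("ORF invariants hold: in-frame stops, monotonicity, table nesting", {
  withr::local_seed(77)
  t1 <- genetic_code(1); t4 <- genetic_code(4)
  for (i in 1:15) {
    s <- random_dna_str(800)
    o1 <- find_orfs(c(x = s), t1, min_len_aa = 20, completeness = "complete")
    o4 <- find_orfs(c(x = s), t4, min_len_aa = 20, completeness = "complete")
    # proteins never contain a stop symbol
    expect_false(any(grepl("\\*", c(o1$protein, o4$protein))))
    # every complete ORF is immediately followed by its in-frame stop codon
    for (k in seq_len(nrow(o1))) {
      span <- if (o1$strand[k] == "+") substr(s, o1$start[k] + 1, o1$end[k])
              else reverse_complement(substr(s, o1$start[k] + 1, o1$end[k]))
      expect_true(substr(span, nchar(span) - 2, nchar(span)) %in% t1$stop_codons)
      expect_equal(nchar(span) %% 3, 0)
      expect_equal(o1$length_aa[k], nchar(span) / 3 - 1)
    }
    # raising the threshold never adds ORFs
    o1b <- find_orfs(c(x = s), t1, min_len_aa = 40, completeness = "complete")
    expect_true(nrow(o1b) <= nrow(o1))
    expect_true(all(paste(o1b$start, o1b$end, o1b$strand) %in%
                      paste(o1$start, o1$end, o1$strand)))
    # every table-1 complete ORF is contained in a table-4 ORF of equal or
    # greater extent (table 4's stop set is a subset; reading through a TGA
    # can run off the contig edge, so partial records count here)
    o4all <- find_orfs(c(x = s), t4, min_len_aa = 20)
    for (k in seq_len(nrow(o1))) {
      same_frame <- o4all[o4all$strand == o1$strand[k] &
                            o4all$frame == o1$frame[k], ]
      containing <- same_frame[same_frame$start <= o1$start[k] &
                                 same_frame$end >= o1$end[k], ]
      expect_true(nrow(containing) >= 1)
    }
  }
})

test_that("longest-ORF mode recovers start-codon-free calling", {
  # no ATG anywhere: strict mode finds nothing, relaxed mode reports the
  # stop-to-stop stretch
  s <- c(x = paste0("TAA", strrep("GCA", 50), "TAG"))
  strict <- find_orfs(s, genetic_code(1), min_len_aa = 10)
  relaxed <- find_orfs(s, genetic_code(1), min_len_aa = 10, require_start = FALSE)
  expect_equal(nrow(strict[strict$completeness == "complete" &
                             strict$strand == "+" & strict$frame == 0, ]), 0L)
  rc <- relaxed[relaxed$completeness == "complete" & relaxed$strand == "+" &
                  relaxed$frame == 0, ]
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$length_aa, 50L)
})

test_that("ORFs serialise to GFF3 and protein FASTA", {
  contig <- c(forced = paste0("ATG", strrep("GCA", 120), "TAA"))
  orfs <- find_orfs(contig, genetic_code(1), completeness = "complete")
  gff <- withr::local_tempfile(fileext = ".gff3")
  faa <- withr::local_tempfile(fileext = ".faa")
  write_orfs(orfs, gff, faa)
  expect_match(readLines(gff)[2], "completeness=complete")
  aa <- Biostrings::readAAStringSet(faa)
  expect_equal(as.character(aa[[1]]), orfs$protein[1])
})
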