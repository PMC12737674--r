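std_row <- function(q = "c1", s = "s1", pid = 50, alen = 100, qs = 1, qe = 100,
                    ev = 1e-20, bs = 100) {
  paste(q, s, pid, alen, 5, 0, qs, qe, 1, alen, format(ev), bs, sep = "\t")
}

test_that("hit tables parse in declared dialects with sentinel fill", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(std_row(), f)
  h <- read_hit_table(f, "outfmt6")
  expect_equal(nrow(h), 1)
  expect_equal(h$subject_title, "unknown")
  expect_equal(h$subject_organism, "unknown")
  expect_true(is.na(h$query_coverage))

  writeLines(paste(std_row(), 95.5, "Botrytis cinerea mitovirus 1",
                   "Botrytis cinerea mitovirus 1", sep = "\t"), f)
  h <- read_hit_table(f, "outfmt6_extended")
  expect_equal(h$query_coverage, 95.5)
  expect_match(h$subject_title, "mitovirus")

  file.create(f2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_equal(nrow(read_hit_table(f2, "outfmt6")), 0)
})

test_that("hit-table structural errors name the offending row", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(std_row(), paste("q", "s", 90, sep = "\t")), f)
  expect_error(read_hit_table(f, "outfmt6"), "row 2")
  writeLines(gsub("^(c1\ts1\t)50", "\\1abc", std_row()), f)
  expect_error(read_hit_table(f, "outfmt6"), "non-numeric.*percent_identity")
})

test_that("best hit selection follows evalue then bitscore tie-breaks", {
  h <- dplyr::bind_rows(
    viromine:::new_hit("q1", "sA", "t", "o", 90, 100, 1e-50, 180),
    viromine:::new_hit("q1", "sB", "t", "o", 95, 100, 1e-10, 300),
    viromine:::new_hit("q2", "sC", "t", "o", 90, 100, 1e-20, 200),
    viromine:::new_hit("q2", "sD", "t", "o", 80, 100, 1e-20, 180))
  b <- best_hit_per_query(h)
  expect_equal(b$subject_id[b$query_id == "q1"], "sA")   # lower evalue
  expect_equal(b$subject_id[b$query_id == "q2"], "sC")   # higher bitscore
})

test_that("best hit equals a brute-force scan over a random table", {
  withr::local_seed(31)
  n <- 120
  h <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    viromine:::new_hit(sprintf("q%d", sample(1:20, 1)), sprintf("s%03d", i),
                       "t", "o", runif(1, 30, 100), 100,
                       10^-sample(5:60, 1), sample(c(100, 200, 300), 1))))
  got <- best_hit_per_query(h)
  for (q in unique(h$query_id)) {
    sub <- h[h$query_id == q, ]
    best <- sub[sub$evalue == min(sub$evalue), ]
    best <- best[best$bitscore == max(best$bitscore), ]
    best <- best[best$percent_identity == max(best$percent_identity), ]
    best <- best[order(best$subject_id), ][1, ]
    expect_equal(got$subject_id[got$query_id == q], best$subject_id)
  }
})

make_triage_fixture <- function() {
  orf <- paste0("ATG", strrep("GCA", 150), "TAA")
  contigs <- viromine:::new_contig_tbl(
    c("virus1", "noorf1", "unann1", "diverg1", "host1"),
    c(paste0(strrep("T", 30), orf),
      strrep("TAGC", 60),                       # no long ORF
      paste0(strrep("C", 30), orf),
      paste0(strrep("G", 30), orf),
      paste0(strrep("A", 30), orf)))
  hits <- dplyr::bind_rows(
    viromine:::new_hit("virus1", "MT119677",
                       "Botrytis cinerea mitovirus 1 isolate BCS1_DN4879",
                       "Botrytis cinerea mitovirus 1", 98, 500, 1e-80, 300),
    viromine:::new_hit("noorf1", "XP_1", "hypothetical protein",
                       "Botrytis cinerea", 99, 240, 1e-30, 150),
    viromine:::new_hit("diverg1", "AAF89327.2",
                       "hypothetical protein [Trichoderma harzianum]",
                       "Trichoderma harzianum", 45, 500, 1e-25, 120),
    viromine:::new_hit("host1", "XP_2", "hypothetical protein BCIN_00001",
                       "Botrytis cinerea", 98, 500, 1e-90, 400))
  list(contigs = contigs, hits = hits)
}

test_that("triage categories follow the documented precedence", {
  fx <- make_triage_fixture()
  orfs1 <- find_orfs(fx$contigs, genetic_code(1), completeness = "complete")
  orfs4 <- find_orfs(fx$contigs, genetic_code(4), completeness = "complete")
  dec <- triage_contigs(fx$contigs, list(orfs1, orfs4),
                        best_hit_per_query(fx$hits))
  got <- stats::setNames(dec$category, dec$contig_id)
  expect_equal(unname(got["virus1"]), "virus_candidate")
  expect_equal(unname(got["noorf1"]), "followup_no_orf")  # ORF rule precedes hit rules
  expect_equal(unname(got["unann1"]), "followup_unannotated_orf")
  expect_equal(unname(got["diverg1"]), "followup_divergent_hit")
  expect_equal(unname(got["host1"]), "host_like")
  # exhaustive and mutually exclusive
  expect_equal(sort(dec$contig_id), sort(fx$contigs$id))
  expect_true(all(dec$category %in% viromine:::TRIAGE_CATEGORIES))
})

test_that("keyword matching is case-insensitive and matches inside words", {
  fx <- make_triage_fixture()
  fx$hits$subject_title[fx$hits$query_id == "host1"] <-
    "Botryotinia fuckeliana PARTITIVIRUS 1 coat protein"
  orfs1 <- find_orfs(fx$contigs, genetic_code(1), completeness = "complete")
  dec <- triage_contigs(fx$contigs, list(orfs1), best_hit_per_query(fx$hits))
  expect_equal(dec$category[dec$contig_id == "host1"], "virus_candidate")
})

test_that("a hit for an unknown contig is an error", {
  fx <- make_triage_fixture()
  bad <- dplyr::bind_rows(fx$hits,
                          viromine:::new_hit("ghost", "s", "t", "o", 50, 100, 1e-5, 50))
  orfs1 <- find_orfs(fx$contigs, genetic_code(1), completeness = "complete")
  expect_error(triage_contigs(fx$contigs, list(orfs1), best_hit_per_query(bad)),
               "ghost")
})

test_that("end contamination flags terminal host hits only", {
  withr::local_seed(9)
  contig <- stats::setNames(random_dna_str(3000), "c1")
  host_hit <- function(qs, qe, pid = 99)
    viromine:::new_hit("c1", "scaf1", "Botrytis cinerea scaffold",
                       "Botrytis cinerea", pid, 3000, 0, 500,
                       query_start = qs, query_end = qe)
  expect_equal(flag_end_contamination(contig, host_hit(2701, 3000))$flag, "right")
  expect_equal(flag_end_contamination(contig, host_hit(1, 320))$flag, "left")
  expect_equal(flag_end_contamination(contig, host_hit(1, 3000))$flag, "none")
  expect_equal(flag_end_contamination(contig, host_hit(1400, 1700))$flag, "none")
  expect_equal(flag_end_contamination(contig, host_hit(2701, 3000, pid = 80))$flag,
               "none")  # below identity floor
  expect_equal(flag_end_contamination(contig, NULL)$flag, "none")
  both <- dplyr::bind_rows(host_hit(1, 350), host_hit(2650, 3000))
  expect_equal(flag_end_contamination(contig, both)$flag, "both")
})
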