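test_that("identity and coverage behave on simple pairs", {
  s <- strrep("ACGTT", 20)
  st <- pairwise_stats(s, s)
  expect_equal(st$identity, 100)
  expect_equal(st$coverage, 100)
  # one substitution in 8: 7/8 matching columns
  st <- pairwise_stats("ACGTACGT", "ACGAACGT")
  expect_equal(st$identity, 87.5)
  expect_equal(st$coverage, 100)
  # a perfect internal fragment covers the shorter sequence fully
  st <- pairwise_stats(substr(s, 21, 60), s)
  expect_equal(st$identity, 100)
  expect_equal(st$coverage, 100)
  expect_error(pairwise_stats("ACGT", "MKLV"), "alphabet")
})

test_that("aligner agrees with the full-matrix DP oracle on random pairs", {
  withr::local_seed(19)
  for (i in 1:40) {
    a <- random_dna_str(sample(5:30, 1))
    b <- random_dna_str(sample(5:30, 1))
    got <- viromine:::align_pair_cpp(a, b, 1, -1, -2, -1, "overlap")
    want <- align_oracle_dp(a, b)
    expect_equal(got$score, want$score, info = paste(a, b))
    expect_equal(got$matches, want$matches, info = paste(a, b))
    expect_equal(got$columns, want$columns, info = paste(a, b))
    expect_equal(got$a_start, want$a_start, info = paste(a, b))
    expect_equal(got$b_start, want$b_start, info = paste(a, b))
    expect_equal(got$a_end, want$a_end, info = paste(a, b))
    expect_equal(got$b_end, want$b_end, info = paste(a, b))
  }
})

test_that("aligner optimum matches exhaustive enumeration on tiny pairs", {
  withr::local_seed(23)
  for (i in 1:25) {
    a <- random_dna_str(sample(3:8, 1))
    b <- random_dna_str(sample(3:8, 1))
    got <- viromine:::align_pair_cpp(a, b, 1, -1, -2, -1, "overlap")
    want <- align_enumerate(a, b)
    expect_equal(got$score, want$score, info = paste(a, b))
    expect_equal(got$matches, want$matches, info = paste(a, b))
    expect_equal(got$columns, want$columns, info = paste(a, b))
  }
})

test_that("local mode finds an embedded exact repeat", {
  withr::local_seed(4)
  core <- random_dna_str(30)
  a <- paste0(random_dna_str(20), core, random_dna_str(20))
  b <- paste0(random_dna_str(10), core, random_dna_str(35))
  st <- pairwise_stats(a, b, mode = "local")
  expect_true(st$identity >= 95)
  expect_true(st$alignment_length >= 30)
})

test_that("trivial clustering cases", {
  expect_equal(length(greedy_cluster(c(a = "ACGTACGTGG", b = "ACGTACGTGG"))$representatives), 1)
  withr::local_seed(8)
  x <- random_dna_str(120); y <- random_dna_str(120)
  st <- pairwise_stats(x, y)
  expect_true(st$identity < 95)   # random pair sits far below threshold
  expect_equal(length(greedy_cluster(c(a = x, b = y))$representatives), 2)
})

test_that("cluster invariants hold on a generated redundant set", {
  rs <- make_redundant_set(seed = 5, n_seeds = 6, n_copies = 24,
                           len_range = c(300, 500))
  cl <- greedy_cluster(rs$sequences)
  expect_equal(length(cl$representatives), 6)
  # membership is a partition
  expect_setequal(cl$membership$member_id, names(rs$sequences))
  expect_true(all(cl$membership$representative_id %in% cl$representatives))
  # every member satisfies both thresholds to its representative
  memb <- cl$membership[cl$membership$member_id != cl$membership$representative_id, ]
  for (k in seq_len(nrow(memb))) {
    st <- pairwise_stats(rs$sequences[[memb$member_id[k]]],
                         rs$sequences[[memb$representative_id[k]]])
    expect_true(st$identity >= 95 && st$coverage >= 95)
  }
  # representatives are mutually non-redundant
  reps <- cl$representatives
  for (i in seq_along(reps)) for (j in seq_len(i - 1L)) {
    st <- pairwise_stats(rs$sequences[[reps[i]]], rs$sequences[[reps[j]]])
    expect_false(st$identity >= 95 && st$coverage >= 95)
  }
  # cluster count is monotone non-increasing as thresholds are lowered
  looser <- greedy_cluster(rs$sequences, min_identity = 80, min_coverage = 80)
  expect_true(length(looser$representatives) <= length(cl$representatives))
})

test_that("protein sequences cluster with the same machinery", {
  withr::local_seed(44)
  p <- paste(sample(viromine:::AA20, 200, replace = TRUE), collapse = "")
  p2 <- p
  substr(p2, 10, 10) <- "A"; substr(p2, 50, 50) <- "G"
  cl <- greedy_cluster(c(long = p, var = substr(p2, 3, 198)))
  expect_equal(cl$representatives, "long")
})
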