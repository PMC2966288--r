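test_that("consensus mutation respects the substitution contract", {
  withr::local_seed(61)
  ab <- DNA
  expect_equal(mutate_consensus("ACGTACGTA", 0, "exact", ab),
               list(instance = "ACGTACGTA", positions = integer(0)))
  for (i in 1:200) {
    mut <- mutate_consensus("ACGTACGTA", 2, "exact", ab)
    expect_equal(hamming_distance("ACGTACGTA", mut$instance), 2)
    expect_length(mut$positions, 2)
    # every substituted symbol actually changed
    oc <- strsplit("ACGTACGTA", "")[[1]]
    nc <- strsplit(mut$instance, "")[[1]]
    expect_true(all(oc[mut$positions + 1] != nc[mut$positions + 1]))
  }
  ds <- vapply(1:200, function(i) {
    hamming_distance("ACGTACGTA",
                     mutate_consensus("ACGTACGTA", 2, "uniform", ab)$instance)
  }, 1L)
  expect_true(all(ds <= 2))
  expect_true(length(unique(ds)) > 1)
  expect_error(mutate_consensus("ACG", 3, "exact", ab),
               class = "stemotif_usage_error")
})

test_that("planted instances carry their implants verbatim at the truth offsets", {
  pi <- plant_instance(N = 20, n = 600, sigma = 4, k = 9, m = 2, seed = 7)
  expect_equal(nrow(pi$truth), 20)
  for (i in 1:20) {
    off <- pi$truth$offset[i]
    expect_equal(substr(pi$sequences$seq[i], off + 1, off + 9),
                 pi$truth$instance[i])
    expect_equal(hamming_distance(pi$consensus, pi$truth$instance[i]), 2)
  }
})

test_that("identical seeds give byte-identical FASTA and truth TSV", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_planted(plant_instance(5, 80, 4, 7, 1, seed = 99), d1)
  write_planted(plant_instance(5, 80, 4, 7, 1, seed = 99), d2)
  expect_identical(readLines(file.path(d1, "seqs.fasta")),
                   readLines(file.path(d2, "seqs.fasta")))
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_planted(plant_instance(5, 80, 4, 7, 1, seed = 100), d3)
  expect_false(identical(readLines(file.path(d1, "seqs.fasta")),
                         readLines(file.path(d3, "seqs.fasta"))))
})

test_that("background symbols are uniform within sampling error", {
  pi <- plant_instance(N = 10, n = 1000, sigma = 4, k = 5, m = 1, seed = 13)
  # strip implants; count the remaining background symbols
  counts <- integer(4); names(counts) <- DNA
  for (i in 1:10) {
    ch <- strsplit(pi$sequences$seq[i], "")[[1]]
    ch <- ch[-(pi$truth$offset[i] + (1:5))]
    counts <- counts + table(factor(ch, levels = DNA))
  }
  ntot <- sum(counts)
  expdev <- sqrt(ntot * 0.25 * 0.75)
  expect_true(all(abs(counts - ntot / 4) < 4 * expdev))
})

test_that("search recovers the consensus of a small planted instance", {
  pi <- plant_instance(N = 8, n = 100, sigma = 4, k = 7, m = 1, seed = 21)
  r <- find_motifs(pi$sequences, k = 7, m = 1, quorum = 8)
  expect_true(pi$consensus %in% r$motifs)
  # and brute force agrees exactly
  bf <- bruteforce_motif_search(pi$sequences, 7, 1, 8)
  expect_equal(sort(r$motifs), bf)
})

test_that("selected-set size on a planted instance tracks the analytic estimate", {
  # protein-sized benchmark: the estimate with t = N implants should be
  # within an order of magnitude of the observed |I|
  pi <- plant_instance(N = 20, n = 600, sigma = 20, k = 13, m = 4, seed = 2)
  win <- extract_windows(pi$sequences, 13)
  cs <- select_candidates(win, 8, 20, 20)
  est <- expected_selected_size(20, 13, 4, 600, 20, 20)
  expect_gt(nrow(cs), est / 10)
  expect_lt(nrow(cs), est * 10)
})

test_that("protein-alphabet instances use 20 residues", {
  pi <- plant_instance(N = 4, n = 60, sigma = 20, k = 6, m = 1, seed = 3)
  expect_equal(alphabet(pi$sequences), AA20)
  expect_equal(nchar(pi$consensus), 6)
})
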