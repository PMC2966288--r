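test_that("candidate set construction: self-pairs and pair unions", {
  C1 <- build_candidate_set("acgt", 1, alphabet = DNA_lower <- c("a", "c", "g", "t"))
  expect_setequal(C1$pattern, generate_stems("acgt", "acgt", 1)$pattern)
  expect_equal(nrow(C1), 4 + 1)

  C2 <- build_candidate_set(c("tgt", "tgc"), 2, alphabet = DNA_lower)
  manual <- unique(c(generate_stems("tgt", "tgt", 2)$pattern,
                     generate_stems("tgc", "tgc", 2)$pattern,
                     generate_stems("tgt", "tgc", 2)$pattern))
  expect_setequal(C2$pattern, manual)
})

test_that("every brute-force motif is an instantiation of some candidate stem", {
  set.seed(41)
  for (i in 1:8) {
    N <- sample(2:4, 1); n <- sample(10:25, 1); k <- sample(3:5, 1)
    m <- sample(1:2, 1); if (m >= k) m <- k - 1
    seqs <- random_seq_set(N, n, DNA)
    bf <- bruteforce_motif_search(seqs, k, m, N)
    if (length(bf) == 0) next
    win <- extract_windows(seqs, k)
    I <- suppressWarnings(select_candidates(win, 2 * m, N, N))
    C <- build_candidate_set(I, m)
    inst <- stem_union(C$pattern, DNA)
    expect_true(all(bf %in% inst))
  }
})

test_that("pruning matches the naive masked scan, wildcards included", {
  expect_equal(
    prune_stems(c("ACG"), seq_set(c("a", "b"), c("TACGT", "ACGTT")), 0, 2)$pattern,
    "ACG")
  expect_equal(
    nrow(prune_stems(c("AAAA"), seq_set(c("a", "b"), c("AAAAC", "CCCCC")), 0, 2)),
    0)

  set.seed(43)
  for (i in 1:10) {
    N <- sample(2:5, 1); n <- sample(10:30, 1); k <- sample(3:6, 1)
    m <- sample(0:2, 1); if (m >= k) m <- k - 1
    q <- sample(1:N, 1)
    seqs <- random_seq_set(N, n, DNA)
    # stems with random wildcards
    pats <- vapply(1:15, function(j) {
      ch <- sample(c(DNA, "?"), k, replace = TRUE, prob = c(rep(1, 4), 1.5))
      paste(ch, collapse = "")
    }, "")
    surv <- prune_stems(pats, seqs, m, q)
    cnt <- naive_prune_counts(pats, seqs, m)
    expect_setequal(surv$pattern, unique(pats[cnt >= q]))
    expect_equal(surv$n_records_matched,
                 cnt[match(surv$pattern, pats)])
  }
})

test_that("expansion + verification equals brute force on seeded instances", {
  set.seed(47)
  for (i in 1:6) {
    seqs <- random_seq_set(4, 25, DNA)
    k <- 5; m <- 1
    bf <- bruteforce_motif_search(seqs, k, m, 4)
    win <- extract_windows(seqs, k)
    I <- suppressWarnings(select_candidates(win, 2 * m, 4, 4))
    if (nrow(I) == 0) { expect_length(bf, 0); next }
    C <- build_candidate_set(I, m)
    surv <- prune_stems(C, seqs, m, 4)
    got <- expand_and_verify(surv, seqs, m, 4)
    expect_equal(sort(as.character(got)), bf)
  }
})

test_that("find_motifs end-to-end equals the brute-force oracle", {
  set.seed(53)
  for (i in 1:25) {
    N <- sample(2:5, 1); n <- sample(10:40, 1); k <- sample(3:7, 1)
    m <- sample(0:min(2, k - 1), 1)
    # DNA plus a protein-style alphabet restricted to 6 used symbols
    ab <- if (i %% 3 == 0) AA20[1:6] else DNA
    seqs <- random_seq_set(N, n, ab)
    bf <- bruteforce_motif_search(seqs, k, m, N)
    fm <- suppressWarnings(find_motifs(seqs, k, m, quorum = N))
    expect_equal(sort(fm$motifs), bf,
                 label = sprintf("instance %d (N=%d n=%d k=%d m=%d)", i, N, n, k, m))
    s <- fm$stats
    expect_lte(s$n_selected, s$n_windows)
    expect_lte(s$n_survivors, s$n_candidates)
  }
})

test_that("trivial exact search finds the shared k-mer with its sites", {
  r <- find_motifs(seq_set(c("a", "b"), c("ACG", "ACG")), k = 3, m = 0, quorum = 2)
  expect_equal(r$motifs, "ACG")
  expect_equal(nrow(r$sites), 2)
  expect_equal(r$sites$offset, c(0L, 0L))
  expect_equal(r$sites$distance, c(0L, 0L))
})

test_that("impossible quorum yields an empty result with a warning", {
  s <- seq_set(c("a", "b"), c("AAAA", "CCCC"))
  expect_warning(r <- find_motifs(s, k = 3, m = 0, quorum = 2), "no motif")
  expect_length(r$motifs, 0)
  expect_equal(r$stats$n_selected, 0L)
})

test_that("result is invariant under record permutation", {
  set.seed(59)
  seqs <- random_seq_set(4, 30, DNA)
  perm <- c(3, 1, 4, 2)
  seqs_p <- seq_set(seqs$id[perm], seqs$seq[perm], alphabet = DNA)
  r1 <- suppressWarnings(find_motifs(seqs, 5, 1))
  r2 <- suppressWarnings(find_motifs(seqs_p, 5, 1))
  expect_equal(sort(r1$motifs), sort(r2$motifs))
  expect_equal(r1$stats$n_candidates, r2$stats$n_candidates)
})

test_that("site location: minimal distance, leftmost tie rule, absent hits", {
  s <- seq_set("r", "ATGCA")
  h2 <- locate_sites("TG?", s, 0, wildcard = "?")
  expect_equal(h2$offset, 1L)
  expect_equal(h2$distance, 0L)
  # patterns are matched against the uppercased records, so symbols outside
  # the (uppercase) alphabet are rejected
  expect_error(locate_sites("tg?", s, 0), class = "stemotif_usage_error")

  s2 <- seq_set("r", "ACGACG")
  h3 <- locate_sites("ACG", s2, 1)
  expect_equal(h3$offset, 0L) # leftmost among equal-distance hits
  h4 <- locate_sites("ACG", s2, 1, all_hits = TRUE)
  expect_equal(sort(h4$offset), c(0L, 3L))

  expect_equal(nrow(locate_sites("TTT", seq_set("r", "AAAA", alphabet = DNA), 0)), 0)
})

test_that("bracket consensus of site windows", {
  expect_equal(build_consensus(c("ACG", "ACG")), "ACG")
  expect_equal(build_consensus(c("ACG", "ATG")), "A[CT]G")
  expect_equal(build_consensus(c("AA", "CA", "GA")), "[ACG]A")
  expect_error(build_consensus(character(0)), class = "stemotif_usage_error")
})

test_that("tidy/glance/report writers expose the frozen interface", {
  r <- find_motifs(seq_set(c("a", "b"), c("TACGT", "GACGA")), k = 3, m = 0,
                   quorum = 2)
  td <- tidy(r)
  expect_true(all(c("pattern", "n_wildcards", "n_records_matched",
                    "n_sites", "total_mismatches", "consensus") %in% names(td)))
  expect_equal(glance(r)$n_motifs, length(r$motifs))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_motif_report(r, f)
  rep <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(names(rep), c("pattern", "n_wildcards", "n_records_matched",
                             "total_mismatches_of_primary_sites", "sites"))
  expect_match(rep$sites[1], "^a:1:0;b:1:0$")

  fb <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(r, fb)
  bed <- readr::read_tsv(fb, col_names = FALSE, show_col_types = FALSE)
  expect_equal(ncol(bed), 6)
  expect_equal(bed$X3 - bed$X2, rep(3, nrow(bed)))

  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
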