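test_that("position subsets are complete, lexicographic, 0-based", {
  expect_length(position_subsets(4, 2), 6)
  expect_equal(position_subsets(5, 0), list(integer(0)))
  expect_equal(position_subsets(3, 3), list(0:2))
  ps <- position_subsets(4, 2)
  expect_equal(ps[[1]], c(0L, 1L))
  expect_equal(ps[[6]], c(2L, 3L))
  expect_error(position_subsets(3, 4), class = "stemotif_usage_error")
})

test_that("reduce_kmer deletes positions and keeps order", {
  expect_equal(reduce_kmer("acgt", c(1, 3)), "ag")
  expect_equal(reduce_kmer("acgt", integer(0)), "acgt")
  expect_equal(reduce_kmer("tgt", 2), reduce_kmer("tgc", 2))
  expect_error(reduce_kmer("acg", 3), class = "stemotif_usage_error")
})

test_that("grouping by reduction groups exactly the removed-confined mismatches", {
  g <- group_by_reduced(c("tgt", "tgc", "aaa"), 2)
  expect_equal(g, list(c(1L, 2L), 3L))
  # all positions removed: one group
  expect_equal(group_by_reduced(c("ab", "cd", "ef"), 0:1), list(1:3))

  set.seed(5)
  for (i in 1:10) {
    k <- sample(3:7, 1)
    kmers <- vapply(1:12, function(j) random_string(k, DNA), "")
    rem <- sort(sample(0:(k - 1), sample(0:k, 1)))
    g <- group_by_reduced(kmers, rem)
    same <- function(a, b) {
      mm <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) - 1L
      all(mm %in% rem)
    }
    for (grp in g) {
      for (a in grp) for (b in grp) expect_true(same(kmers[a], kmers[b]))
    }
    # across groups: some mismatch outside removed
    if (length(g) > 1) {
      expect_false(same(kmers[g[[1]][1]], kmers[g[[2]][1]]))
    }
  }
})

test_that("select_candidates matches the trivial contracts", {
  s <- seq_set("solo", "ACGTACG")
  w <- extract_windows(s, 3)
  cs <- select_candidates(w, 2, 1, 1)
  expect_equal(nrow(cs), nrow(w)) # own record always matched at q = 1

  s2 <- seq_set(c("a", "b"), c("ACGT", "CGTA"))
  w2 <- extract_windows(s2, 3)
  cs2 <- select_candidates(w2, 0, 2, 2)
  expect_setequal(unique(cs2$kmer), "CGT")
  expect_true(all(cs2$n_matched >= 2))
  # the occurrence's own record is always in its mask
  expect_true(all(mapply(function(m, r) r %in% m, cs2$match_mask, cs2$seq_index)))

  expect_error(select_candidates(w2, 2, 3, 2), class = "stemotif_usage_error")
  expect_warning(select_candidates(w2, 3, 2, 2), "degenerate")
})

test_that("selection equals the naive quadratic scan on random instances", {
  set.seed(17)
  for (i in 1:30) {
    N <- sample(2:6, 1); n <- sample(8:40, 1); k <- sample(3:8, 1)
    d <- sample(0:4, 1); q <- sample(1:N, 1)
    seqs <- random_seq_set(N, n, DNA)
    win <- extract_windows(seqs, k)
    cs <- suppressWarnings(select_candidates(win, d, q, N))
    cnt <- naive_select_counts(win, min(d, k), N)
    expect_equal(which(cnt >= q),
                 which(seq_len(nrow(win)) %in%
                         match(paste(cs$kmer, cs$seq_index, cs$offset),
                               paste(win$kmer, win$seq_index, win$offset))))
    expect_equal(cs$n_matched, cnt[cnt >= q])
  }
})

test_that("selected set grows with d and shrinks with q", {
  set.seed(23)
  seqs <- random_seq_set(4, 30, DNA)
  win <- extract_windows(seqs, 5)
  sizes_d <- vapply(0:4, function(d) {
    nrow(suppressWarnings(select_candidates(win, d, 3, 4)))
  }, 1L)
  expect_true(all(diff(sizes_d) >= 0))
  sizes_q <- vapply(1:4, function(q) {
    nrow(suppressWarnings(select_candidates(win, 2, q, 4)))
  }, 1L)
  expect_true(all(diff(sizes_q) <= 0))
})
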