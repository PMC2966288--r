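test_that("hamming distance basics and error contract", {
  expect_equal(hamming_distance("tgt", "tgt"), 0)
  expect_equal(hamming_distance("tgt", "tgc"), 1)
  expect_equal(hamming_distance("aaa", "ccc"), 3)
  expect_equal(hamming_distance(c("ab", "ab"), c("ab", "ba")), c(0, 2))
  expect_error(hamming_distance("ab", "abc"), class = "stemotif_usage_error")
})

test_that("neighborhood size formula matches exhaustive enumeration", {
  expect_equal(neighborhood_size(7, 0, 4), 1)
  expect_equal(neighborhood_size(1, 1, 4), 4)
  # V(9,2,4) by brute force
  nb <- enumerate_neighborhood(strrep("a", 9), 2, letters[1:4])
  expect_equal(neighborhood_size(9, 2, 4), length(nb))
  expect_equal(length(nb), 352)

  set.seed(11)
  for (i in 1:12) {
    sg <- sample(c(2, 4, 6), 1)
    k <- sample(2:6, 1)
    m <- sample(0:min(3, k), 1)
    ab <- letters[1:sg]
    x <- random_string(k, ab)
    nbh <- enumerate_neighborhood(x, m, ab)
    expect_equal(length(nbh), neighborhood_size(k, m, sg))
    expect_equal(anyDuplicated(nbh), 0)
    expect_true(all(hamming_distance(rep(x, length(nbh)), nbh) <= m))
  }
})

test_that("neighborhood enumeration trivial cases", {
  expect_equal(enumerate_neighborhood("acg", 0, c("a", "c", "g", "t")), "acg")
  expect_equal(length(enumerate_neighborhood("aa", 2, c("a", "c"))), 4)
  expect_equal(length(enumerate_neighborhood("aa", 1, letters[1:4])), 7)
  expect_error(enumerate_neighborhood("axz", 1, c("a", "c")),
               class = "stemotif_usage_error")
  expect_error(enumerate_neighborhood(strrep("A", 30), 10, AA20),
               class = "stemotif_capacity_error")
})

test_that("neighborhood intersection oracle: fixed case, symmetry, far pairs", {
  ab <- letters[c(1, 3, 7, 20)] # a c g t
  iv <- intersect_neighborhoods_bruteforce("tgt", "tgc", 2, ab)
  expect_equal(length(iv), 28)
  expect_true(all(substr(iv, 1, 1) == "t" | substr(iv, 2, 2) == "g"))

  expect_equal(intersect_neighborhoods_bruteforce("acg", "gca", 2, ab),
               intersect_neighborhoods_bruteforce("gca", "acg", 2, ab))
  expect_equal(intersect_neighborhoods_bruteforce("acg", "acg", 1, ab),
               enumerate_neighborhood("acg", 1, ab))
  # distance 3 > 2m = 2: empty
  expect_length(intersect_neighborhoods_bruteforce("aaa", "ccc", 1, ab), 0)
})

test_that("brute-force motif search ground truths", {
  s <- seq_set(c("a", "b"), c("ACG", "ACG"))
  expect_equal(bruteforce_motif_search(s, 3, 0, 2), "ACG")

  # m = 0, q = N equals the verbatim common k-mers
  set.seed(3)
  s2 <- random_seq_set(3, 25, c("A", "C"))
  bf <- bruteforce_motif_search(s2, 3, 0, 3)
  w <- extract_windows(s2, 3)
  common <- Reduce(intersect, split(w$kmer, w$seq_index))
  expect_setequal(bf, common)

  expect_error(bruteforce_motif_search(random_seq_set(2, 30, AA20), 13, 4, 2),
               class = "stemotif_capacity_error")
})
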