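test_that("masked distance counts non-wildcard mismatches only", {
  expect_equal(stem_distance("tg?", "tgc"), 0)
  expect_equal(stem_distance("t?c", "tgt"), 1)
  expect_equal(stem_distance("???", "xyz"), 0)
  expect_error(stem_distance("t?", "tgc"), class = "stemotif_usage_error")
})

test_that("stem generation reproduces the worked pair example", {
  gs <- generate_stems("tgt", "tgc", 2)
  expect_equal(nrow(gs), 9)
  expect_true(all(c("tg?", "t??", "?g?", "t?c", "?gc") %in% gs$pattern))
  expect_equal(anyDuplicated(gs$pattern), 0)
  expect_true(all(gs$n_wildcards <= 2))
  # exact coverage of the 28-member intersection
  ab <- c("a", "c", "g", "t")
  expect_equal(stem_union(gs$pattern, ab),
               intersect_neighborhoods_bruteforce("tgt", "tgc", 2, ab))
})

test_that("identical pair at m = 1 yields one wildcard per position plus itself", {
  gs <- generate_stems("acg", "acg", 1)
  expect_setequal(gs$pattern, c("acg", "?cg", "a?g", "ac?"))
  expect_equal(nrow(gs), 3 + 1)
})

test_that("pairs beyond distance 2m share no stems", {
  expect_equal(nrow(generate_stems("aaa", "ccc", 1)), 0)
  expect_equal(count_stems(3, 3, 1), 0)
})

test_that("stem instantiations equal the neighborhood intersection (randomized)", {
  set.seed(31)
  for (i in 1:40) {
    sg <- sample(c(2, 4, 20), 1)
    ab <- if (sg == 20) AA20 else DNA[1:sg]
    k <- if (sg == 20) sample(3:5, 1) else sample(3:8, 1)
    m <- sample(1:min(3, k - 1), 1)
    if (sg == 20 && m == 3) k <- min(k, 4)
    a <- random_string(k, ab)
    b <- random_string(k, ab)
    gs <- generate_stems(a, b, m)
    expect_true(all(gs$n_wildcards <= m))
    expect_equal(stem_union(gs$pattern, ab),
                 intersect_neighborhoods_bruteforce(a, b, m, ab),
                 label = sprintf("pair (%s, %s), m = %d, sigma = %d", a, b, m, sg))
  }
})

test_that("closed-form stem count matches the generator and printed special case", {
  for (k in 3:12) expect_equal(count_stems(k, 0, 1), k + 1)
  expect_equal(count_stems(3, 1, 2), 9)

  set.seed(37)
  for (i in 1:25) {
    k <- sample(3:8, 1)
    m <- sample(1:min(3, k - 1), 1)
    d <- sample(0:min(k, 2 * m), 1)
    # force a pair at distance exactly d
    a <- random_string(k, DNA)
    bc <- strsplit(a, "")[[1]]
    for (p in sample(k, d)) bc[p] <- setdiff(DNA, bc[p])[sample(3, 1)]
    b <- paste(bc, collapse = "")
    expect_equal(nrow(generate_stems(a, b, m)), count_stems(k, d, m),
                 label = sprintf("k=%d d=%d m=%d", k, d, m))
  }
})

test_that("stem patterns are identical regardless of the ambient alphabet", {
  gs_dna <- generate_stems("ACT", "ACG", 2)
  expect_equal(nrow(gs_dna), count_stems(3, 1, 2)) # count has no alphabet argument
  # the same patterns expand correctly over a 20-symbol ambient alphabet
  inst20 <- stem_union(gs_dna$pattern, AA20)
  expect_equal(inst20, intersect_neighborhoods_bruteforce("ACT", "ACG", 2, AA20))
})

test_that("instantiation expands wildcards over the alphabet under a cap", {
  expect_equal(instantiate_stem("tg?", letters[c(1, 3, 7, 20)]),
               c("tga", "tgc", "tgg", "tgt"))
  expect_equal(instantiate_stem("tgc", DNA), "tgc")
  expect_error(instantiate_stem("??????", DNA, cap = 10),
               class = "stemotif_capacity_error")
})

test_that("subsumption and minimization", {
  expect_true(subsumes("tg?", "tgt"))
  expect_true(subsumes("t??", "tg?"))
  expect_false(subsumes("t??", "?gc"))
  expect_false(subsumes("tgt", "tg?"))

  expect_equal(minimize_stems(c("tg?", "t??"))$pattern, "t??")
  # subsumption-minimal set of the 9 stems of (tgt, tgc): the pair
  # {t??, ?g?} already covers the whole intersection
  m9 <- minimize_stems(generate_stems("tgt", "tgc", 2))
  expect_setequal(m9$pattern, c("t??", "?g?"))
  expect_equal(stem_union(m9$pattern, c("a", "c", "g", "t")),
               intersect_neighborhoods_bruteforce("tgt", "tgc", 2,
                                                  c("a", "c", "g", "t")))
  # idempotence
  expect_equal(minimize_stems(m9)$pattern, m9$pattern)
})
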