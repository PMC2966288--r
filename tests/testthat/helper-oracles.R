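# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (vectorised R, no shared code with the fast paths).

DNA <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_seq_set <- function(N, n, alphabet) {
  seq_set(paste0("s", seq_len(N)),
          vapply(seq_len(N), function(i) random_string(n, alphabet), ""),
          alphabet = alphabet)
}

# Per-window count of records holding a window within Hamming distance d:
# the quadratic scan the counting-sort selection must reproduce.
naive_select_counts <- function(win, d, N) {
  vapply(seq_len(nrow(win)), function(wi) {
    sum(vapply(0:(N - 1), function(r) {
      wr <- win$kmer[win$seq_index == r]
      length(wr) > 0 &&
        any(hamming_distance(rep(win$kmer[wi], length(wr)), wr) <= d)
    }, TRUE))
  }, 1L)
}

# Per-pattern count of records with a window at masked distance <= m:
# ground truth for stem pruning.
naive_prune_counts <- function(patterns, seqs, m, wildcard = "?") {
  k <- nchar(patterns[1])
  win <- suppressWarnings(extract_windows(seqs, k))
  N <- nrow(seqs)
  vapply(patterns, function(p) {
    sum(vapply(0:(N - 1), function(r) {
      wr <- win$kmer[win$seq_index == r]
      length(wr) > 0 &&
        any(stem_distance(rep(p, length(wr)), wr, wildcard) <= m)
    }, TRUE))
  }, 1L, USE.NAMES = FALSE)
}

# Union of stem instantiations, as a sorted character vector.
stem_union <- function(patterns, alphabet, wildcard = "?") {
  out <- unlist(lapply(patterns, instantiate_stem, alphabet = alphabet,
                       cap = 1e7, wildcard = wildcard))
  sort(unique(as.character(out)))
}
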