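#' Hamming distance between equal-length strings
#'
#' @param a,b Character vectors of equal-length strings (recycled pairwise).
#' @return Integer vector of mismatch counts.
#' @examples
#' hamming_distance("tgt", "tgc")
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    abort_usage("hamming distance requires equal-length strings")
  }
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

#' Size of a Hamming neighborhood
#'
#' Number of k-mers over an alphabet of `sigma` symbols at Hamming distance at
#' most `m` from a fixed k-mer: `sum_{i=0..m} C(k,i) (sigma-1)^i`. This count
#' grows with the alphabet size, which is what makes explicit neighborhood
#' enumeration expensive for protein-scale alphabets.
#'
#' @param k Word length.
#' @param m Maximum mismatches (`0 <= m <= k`).
#' @param sigma Alphabet size (`>= 2`).
#' @return Numeric count.
#' @export
neighborhood_size <- function(k, m, sigma) {
  if (m < 0 || m > k) abort_usage("m must satisfy 0 <= m <= k")
  if (sigma < 2) abort_usage("sigma must be at least 2")
  sum(choose(k, 0:m) * (sigma - 1)^(0:m))
}

#' Enumerate a Hamming neighborhood (brute-force oracle)
#'
#' Returns exactly the set of k-mers at distance at most `m` from `x`, with no
#' duplicates. Exponential by design; refuses candidate spaces above the guard
#' unless `allow_large = TRUE`.
#'
#' @param x A k-mer over `alphabet`.
#' @param m Maximum mismatches.
#' @param alphabet Character vector of symbols.
#' @param allow_large Lift the size guard.
#' @return Character vector of neighbors (sorted), including `x`.
#' @export
enumerate_neighborhood <- function(x, m, alphabet, allow_large = FALSE) {
  k <- nchar(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  if (any(!chars %in% alphabet)) {
    abort_usage("x contains symbols outside the alphabet")
  }
  if (m < 0 || m > k) abort_usage("m must satisfy 0 <= m <= k")
  v <- neighborhood_size(k, m, length(alphabet))
  if (!allow_large && v > 5e6) {
    abort_capacity(sprintf(
      "neighborhood of %.3g k-mers exceeds the oracle guard; set allow_large = TRUE", v))
  }
  res <- list(x)
  for (i in seq_len(m)) {
    subs <- utils::combn(k, i)
    for (ci in seq_len(ncol(subs))) {
      pos <- subs[, ci]
      grid <- expand.grid(lapply(pos, function(p) setdiff(alphabet, chars[p])),
                          stringsAsFactors = FALSE)
      mat <- matrix(chars, nrow = nrow(grid), ncol = k, byrow = TRUE)
      mat[, pos] <- as.matrix(grid)
      res[[length(res) + 1L]] <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
    }
  }
  sort(unique(unlist(res)))
}

#' Intersection of two Hamming neighborhoods (brute-force oracle)
#'
#' The set of k-mers within distance `m` of both `a` and `b`; ground truth for
#' the wildcard-stem generator.
#'
#' @param a,b Equal-length k-mers.
#' @param m Maximum mismatches.
#' @param alphabet Character vector of symbols.
#' @param allow_large Lift the size guard.
#' @return Sorted character vector.
#' @export
intersect_neighborhoods_bruteforce <- function(a, b, m, alphabet,
                                               allow_large = FALSE) {
  if (nchar(a) != nchar(b)) abort_usage("a and b must have equal length")
  na <- enumerate_neighborhood(a, m, alphabet, allow_large = allow_large)
  na[hamming_distance(rep(b, length(na)), na) <= m]
}

#' Brute-force motif search (oracle)
#'
#' Exhaustively finds every k-mer within Hamming distance `m` of at least `q`
#' of the input records. Candidates are enumerated from the neighborhoods of
#' the first record's windows when `q = N` (complete, since a motif must have
#' an instance within `m` of the first record), and from every record's
#' windows otherwise. Exponential by design: refuses large candidate spaces
#' unless `allow_large = TRUE`.
#'
#' @param seqs A `seq_set`.
#' @param k Motif length.
#' @param m Maximum mismatches.
#' @param q Quorum (number of records a motif must match).
#' @param allow_large Lift the size guard.
#' @return Sorted character vector of motif k-mers.
#' @export
bruteforce_motif_search <- function(seqs, k, m, q = nrow(seqs),
                                    allow_large = FALSE) {
  if (nrow(seqs) < 1) abort_usage("empty sequence set")
  N <- nrow(seqs)
  if (q > N || q < 1) abort_usage("q must satisfy 1 <= q <= N")
  ab <- alphabet(seqs)
  if (!allow_large && k * log2(length(ab)) > 30) {
    abort_capacity("candidate space above 2^30; set allow_large = TRUE")
  }
  win <- suppressWarnings(extract_windows(seqs, k))
  src <- if (q == N) win[win$seq_index == win$seq_index[1], ] else win
  cand <- sort(unique(unlist(lapply(
    unique(src$kmer), enumerate_neighborhood, m = m, alphabet = ab,
    allow_large = allow_large))))
  if (length(cand) == 0) return(character(0))

  cm <- char_matrix(cand, k)
  n_match <- integer(length(cand))
  for (s in unique(win$seq_index)) {
    wk <- unique(win$kmer[win$seq_index == s])
    wm <- char_matrix(wk, k)
    d <- matrix(0L, length(cand), length(wk))
    for (j in seq_len(k)) {
      d <- d + outer(cm[j, ], wm[j, ], "!=")
    }
    n_match <- n_match + (apply(d, 1, min) <= m)
  }
  cand[n_match >= q]
}
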