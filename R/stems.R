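#' Masked Hamming distance between a wildcard pattern and a window
#'
#' Counts mismatches at the non-wildcard positions only; wildcard positions
#' match any symbol for free.
#'
#' @param stem Character vector of patterns (wildcard character `?`).
#' @param window Character vector of windows, recycled pairwise.
#' @param wildcard Wildcard character used in `stem`.
#' @return Integer vector of mismatch counts.
#' @examples
#' stem_distance("t?c", "tgt")
#' @export
stem_distance <- function(stem, window, wildcard = WILDCARD) {
  n <- max(length(stem), length(window))
  stem <- rep_len(stem, n)
  window <- rep_len(window, n)
  if (any(nchar(stem) != nchar(window))) {
    abort_usage("stem and window must have equal length")
  }
  wc <- charToRaw(wildcard)
  mapply(function(s, w) {
    sr <- charToRaw(s)
    sum(sr != wc & sr != charToRaw(w))
  }, stem, window, USE.NAMES = FALSE)
}

stem_set_tibble <- function(pattern, n_wildcards, wildcard = WILDCARD) {
  out <- tibble(pattern = pattern, n_wildcards = n_wildcards)
  class(out) <- c("stem_set", class(out))
  attr(out, "wildcard") <- wildcard
  out
}

#' Generate the wildcard stems shared by a pair of k-mers
#'
#' Enumerates the set of length-k wildcard patterns (stems) whose
#' instantiations are exactly the k-mers within Hamming distance `m` of both
#' `a` and `b` — a compressed representation of the pairwise neighborhood
#' intersection whose size depends only on `k`, `m` and the Hamming distance
#' `d(a, b)`, never on the alphabet size. Returns the empty set when
#' `d(a, b) > 2m` (no common neighbor can exist).
#'
#' With `D` the mismatch region (`d = |D|`), the stems are built by choosing
#' `i` positions of `D` carrying `b`'s symbol (`max(0, d-m) <= i <= min(d, m)`),
#' `j1` wildcards in the rest of `D`, and `j2` wildcards in the match region
#' with `j2 <= m - max(i + j1, d - i)`; all remaining positions carry `a`'s
#' symbols.
#'
#' @param a,b Equal-length k-mers.
#' @param m Maximum mismatches (`0 <= m < k`).
#' @param wildcard Wildcard display character.
#' @return A `stem_set` tibble with columns `pattern` and `n_wildcards`.
#' @examples
#' generate_stems("tgt", "tgc", 2)
#' @export
generate_stems <- function(a, b, m, wildcard = WILDCARD) {
  if (nchar(a) != nchar(b)) abort_usage("a and b must have equal length")
  k <- nchar(a)
  if (m < 0 || m >= k) abort_usage("m must satisfy 0 <= m < k")
  ab <- sort(unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1]]))
  if (length(ab) < 2) ab <- union(ab, if ("A" %in% ab) "B" else "A")
  res <- cpp_gen_pair(encode_kmers(a, ab), encode_kmers(b, ab),
                      length(ab), as.integer(m))
  pat <- decode_kmers(res$stems, k, ab, wildcard)
  out <- stem_set_tibble(pat, res$n_wildcards, wildcard)
  attr(out, "provenance") <- c(a = a, b = b)
  out
}

#' Closed-form count of stems for a pair at Hamming distance d
#'
#' Equals `nrow(generate_stems(a, b, m))` for any pair at distance `d`;
#' independent of the alphabet size (the function takes no alphabet
#' argument). Zero when `d > 2m`.
#'
#' @param k Word length.
#' @param d Hamming distance between the pair (`0 <= d <= k`).
#' @param m Maximum mismatches (`0 <= m < k`).
#' @return Numeric count.
#' @examples
#' count_stems(3, 1, 2)  # the 9 stems of e.g. ("tgt", "tgc")
#' @export
count_stems <- function(k, d, m) {
  if (d < 0 || d > k) abort_usage("d must satisfy 0 <= d <= k")
  if (m < 0 || m >= k) abort_usage("m must satisfy 0 <= m < k")
  if (d > 2 * m) return(0)
  total <- 0
  for (i in max(0, d - m):min(d, m)) {
    for (j1 in 0:(d - i)) {
      jmax <- m - max(i + j1, d - i)
      if (jmax < 0) next
      for (j2 in 0:jmax) {
        total <- total + choose(d, i) * choose(d - i, j1) * choose(k - d, j2)
      }
    }
  }
  total
}

#' Expand a stem into its explicit k-mers
#'
#' Substitutes every alphabet symbol at each wildcard position, yielding
#' `sigma^n_wildcards` k-mers.
#'
#' @param stem A single pattern string.
#' @param alphabet Character vector of symbols.
#' @param cap Refuse expansions larger than this many k-mers.
#' @param wildcard Wildcard character.
#' @return Sorted character vector of k-mers.
#' @export
instantiate_stem <- function(stem, alphabet, cap = 1e6, wildcard = WILDCARD) {
  if (cap < 1) abort_usage("cap must be at least 1")
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  wp <- which(chars == wildcard)
  total <- length(alphabet)^length(wp)
  if (total > cap) {
    abort_capacity(sprintf(
      "stem '%s' expands to %.3g k-mers, above the cap of %.3g", stem, total, cap))
  }
  if (length(wp) == 0) return(stem)
  grid <- expand.grid(rep(list(alphabet), length(wp)), stringsAsFactors = FALSE)
  mat <- matrix(chars, nrow = nrow(grid), ncol = length(chars), byrow = TRUE)
  mat[, wp] <- as.matrix(grid)
  sort(do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE)))
}

#' Does one stem subsume another?
#'
#' `outer` subsumes `inner` when every instantiation of `inner` is an
#' instantiation of `outer`: at every non-wildcard position of `outer`,
#' `inner` carries the same (non-wildcard) symbol.
#'
#' @param outer,inner Pattern strings of equal length (vectors recycled).
#' @param wildcard Wildcard character.
#' @return Logical vector.
#' @export
subsumes <- function(outer, inner, wildcard = WILDCARD) {
  n <- max(length(outer), length(inner))
  outer <- rep_len(outer, n)
  inner <- rep_len(inner, n)
  if (any(nchar(outer) != nchar(inner))) {
    abort_usage("outer and inner must have equal length")
  }
  wc <- charToRaw(wildcard)
  mapply(function(o, i) {
    or <- charToRaw(o)
    ir <- charToRaw(i)
    all(or == wc | (or == ir & ir != wc))
  }, outer, inner, USE.NAMES = FALSE)
}

#' Remove subsumed stems from a stem set
#'
#' Drops every stem subsumed by another member; the union of instantiations
#' is unchanged and the operation is idempotent.
#'
#' @param ss A `stem_set` tibble or character vector of patterns.
#' @param wildcard Wildcard character.
#' @return A `stem_set` tibble.
#' @export
minimize_stems <- function(ss, wildcard = WILDCARD) {
  pat <- if (is.character(ss)) unique(ss) else unique(ss$pattern)
  if (!is.character(ss) && !is.null(attr(ss, "wildcard"))) {
    wildcard <- attr(ss, "wildcard")
  }
  pat <- sort(pat)
  keep <- rep(TRUE, length(pat))
  for (i in seq_along(pat)) {
    others <- pat[keep & seq_along(pat) != i]
    if (length(others) > 0 && any(subsumes(others, pat[i], wildcard))) {
      keep[i] <- FALSE
    }
  }
  nw <- vapply(strsplit(pat[keep], "", fixed = TRUE),
               function(ch) sum(ch == wildcard), 1L)
  stem_set_tibble(pat[keep], nw, wildcard)
}
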