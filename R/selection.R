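#' All position subsets used by the counting-sort selection rounds
#'
#' Selection removes `d` of the `k` positions in every round; the rounds
#' iterate over all `C(k, d)` subsets in lexicographic order so runs are
#' reproducible.
#'
#' @param k Word length.
#' @param d Number of removed positions (`0 <= d <= k`).
#' @return List of integer vectors of 0-based positions.
#' @export
position_subsets <- function(k, d) {
  if (d < 0 || d > k) abort_usage("d must satisfy 0 <= d <= k")
  if (d == 0) return(list(integer(0)))
  m <- utils::combn(k, d) - 1L
  lapply(seq_len(ncol(m)), function(i) m[, i])
}

#' Delete positions from k-mers
#'
#' @param kmer Character vector of k-mers.
#' @param removed Integer vector of 0-based positions to delete.
#' @return The `(k - length(removed))`-mers, original order preserved.
#' @examples
#' reduce_kmer("acgt", c(1, 3))
#' @export
reduce_kmer <- function(kmer, removed) {
  if (length(kmer) == 0) return(character(0))
  k <- nchar(kmer[1])
  removed <- as.integer(removed)
  if (length(removed) > 0 && (min(removed) < 0 || max(removed) >= k)) {
    abort_usage("removed positions must lie in [0, k)")
  }
  keep <- setdiff(seq_len(k), removed + 1L)
  if (length(keep) == 0) return(rep("", length(kmer)))
  cm <- char_matrix(kmer, k)
  do.call(paste0, lapply(keep, function(i) cm[i, ]))
}

#' Group k-mer occurrences by their position-deleted reduction
#'
#' Two occurrences share a group exactly when their reduced strings are equal,
#' i.e. when their mismatches are confined to the removed positions. Grouping
#' uses radix/counting passes over symbol codes (linear in total characters),
#' and group order is deterministic given input order (by first occurrence).
#'
#' @param occurrences Tibble with a `kmer` column (as from
#'   [extract_windows()]), or a character vector of k-mers.
#' @param removed Integer vector of 0-based removed positions.
#' @param alphabet Character vector of symbols; inferred from the k-mers when
#'   `NULL`.
#' @return List of integer vectors of occurrence indices (1-based rows).
#' @export
group_by_reduced <- function(occurrences, removed, alphabet = NULL) {
  kmers <- if (is.character(occurrences)) occurrences else occurrences$kmer
  if (length(kmers) == 0) return(list())
  k <- nchar(kmers[1])
  if (any(nchar(kmers) != k)) abort_usage("all occurrences must share length k")
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(strsplit(kmers, "", fixed = TRUE))))
  }
  cm <- char_matrix(kmers, k)
  codes <- match(cm, alphabet)
  if (anyNA(codes)) abort_usage("occurrence contains a symbol outside the alphabet")
  dim(codes) <- dim(cm)
  keep <- setdiff(seq_len(k), as.integer(removed) + 1L)

  if (length(keep) == 0) return(list(seq_along(kmers)))
  cols <- lapply(keep, function(i) codes[i, ])
  ord <- do.call(order, c(cols, list(method = "radix")))
  key <- do.call(paste, c(cols, list(sep = ".")))
  run_id <- cumsum(!duplicated(key[ord]))[order(ord)]
  # deterministic: groups in order of first appearance in the input
  first <- tapply(seq_along(kmers), run_id, min)
  lvl <- rank(first)
  groups <- split(seq_along(kmers), lvl[run_id])
  unname(groups)
}

#' Select candidate motif instances by counting-sort rounds
#'
#' Finds every k-mer occurrence within Hamming distance `d` of at least `q`
#' input records — the necessary condition (at `d = 2m`) for being a motif
#' instance, since two instances of one motif can disagree in at most `2m`
#' positions. Each of the `C(k, d)` rounds deletes one position subset and
#' groups equal reductions; an occurrence accumulates the records seen in its
#' groups across rounds (per-record matches may be witnessed in different
#' rounds), and is selected when its mask covers at least `q` records. A
#' k-mer's own record always counts (distance 0).
#'
#' @param occurrences Tibble from [extract_windows()] (columns `kmer`,
#'   `seq_index`, `offset`).
#' @param d Distance parameter (use `2m` for motif search).
#' @param q Quorum, `1 <= q <= N`.
#' @param N Number of input records.
#' @param alphabet Character vector of symbols; inferred when `NULL`.
#' @return A `candidate_set` tibble: the selected occurrences with `n_matched`
#'   and a `match_mask` list-column of 0-based record indices.
#' @export
select_candidates <- function(occurrences, d, q, N, alphabet = NULL) {
  if (nrow(occurrences) == 0) abort_usage("occurrences must be nonempty")
  if (q > N || q < 1) abort_usage("q must satisfy 1 <= q <= N")
  k <- nchar(occurrences$kmer[1])
  if (d > k) d <- k
  if (d >= k) {
    warn(sprintf("degenerate parameters (d >= k): every occurrence is selected"))
  }
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(strsplit(occurrences$kmer, "", fixed = TRUE))))
  }
  codes <- encode_kmers(occurrences$kmer, alphabet, what = "occurrence")
  res <- cpp_match_records(codes, codes, occurrences$seq_index,
                           k, as.integer(d), length(alphabet), as.integer(N),
                           as.integer(q), TRUE)
  sel <- res$counts >= q
  out <- occurrences[sel, , drop = FALSE]
  out$n_matched <- res$counts[sel]
  out$match_mask <- res$masks[sel]
  out <- as_tibble(out)
  class(out) <- c("candidate_set", class(out))
  attr(out, "alphabet") <- alphabet
  attr(out, "d") <- d
  attr(out, "q") <- q
  attr(out, "N") <- N
  attr(out, "n_input") <- nrow(occurrences)
  out
}
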