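#' Build the candidate stem set over pairs of selected k-mers
#'
#' Unions the stem sets of all unordered pairs of distinct selected k-mers at
#' Hamming distance at most `2m` (pairs farther apart share no neighbor),
#' plus the self-pair of every k-mer (its distance-0 stems), deduplicated.
#' Under the `"cross-record"` policy only pairs whose occurrences come from
#' different records are used (self-pairs kept). Every motif attainable from
#' the selected instances is an instantiation of some member of the result.
#'
#' @param I A `candidate_set` from [select_candidates()], or a character
#'   vector of k-mers.
#' @param m Maximum mismatches.
#' @param pair_policy `"all"` (default) or `"cross-record"`.
#' @param alphabet Symbols; taken from `I` or inferred when `NULL`.
#' @param pair_budget Emit a warning when the pair count exceeds this.
#' @param wildcard Wildcard display character.
#' @return A `stem_set` tibble.
#' @export
build_candidate_set <- function(I, m, pair_policy = c("all", "cross-record"),
                                alphabet = NULL, pair_budget = 2e8,
                                wildcard = WILDCARD) {
  pair_policy <- match.arg(pair_policy)
  if (is.character(I)) {
    kmers <- unique(I)
    own_rec <- rep(-1L, length(kmers))
  } else {
    if (nrow(I) == 0) abort_usage("candidate set must be nonempty")
    if (is.null(alphabet)) alphabet <- attr(I, "alphabet")
    kd <- dplyr::distinct(tibble(kmer = I$kmer, rec = I$seq_index))
    nrec <- tapply(kd$rec, kd$kmer, function(r) length(unique(r)))
    kmers <- unique(I$kmer)
    own <- tapply(kd$rec, kd$kmer, function(r) r[1])
    own_rec <- ifelse(nrec[kmers] > 1, -1L, as.integer(own[kmers]))
  }
  if (length(kmers) == 0) abort_usage("candidate set must be nonempty")
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(strsplit(kmers, "", fixed = TRUE))))
  }
  k <- nchar(kmers[1])
  np <- as.numeric(length(kmers))^2
  if (np > pair_budget) {
    warn(sprintf("building stems over ~%.3g k-mer pairs; this may be slow", np / 2))
  }
  res <- cpp_pair_stems(encode_kmers(kmers, alphabet), k, length(alphabet),
                        as.integer(m), as.integer(own_rec),
                        pair_policy == "cross-record")
  out <- stem_set_tibble(decode_kmers(res$stems, k, alphabet, wildcard),
                         res$n_wildcards, wildcard)
  attr(out, "alphabet") <- alphabet
  out
}

#' Prune stems that fail the motif property
#'
#' A stem survives when at least `q` records contain a window at masked
#' Hamming distance at most `m` from it (wildcards match free). Implemented
#' by counting-sort rounds over position-deleted patterns grouped by wildcard
#' layout, with a direct masked scan where that is cheaper; both produce the
#' set defined by the naive scan.
#'
#' @param C A `stem_set` tibble or character vector of patterns.
#' @param seqs A `seq_set`.
#' @param m Maximum mismatches.
#' @param q Quorum.
#' @param wildcard Wildcard character.
#' @return A `stem_set` tibble of survivors with `n_records_matched`.
#' @export
prune_stems <- function(C, seqs, m, q, wildcard = WILDCARD) {
  pat <- if (is.character(C)) C else C$pattern
  if (!is.character(C) && !is.null(attr(C, "wildcard"))) wildcard <- attr(C, "wildcard")
  if (length(pat) == 0) return(stem_set_tibble(character(0), integer(0), wildcard))
  ab <- alphabet(seqs)
  k <- nchar(pat[1])
  win <- suppressWarnings(extract_windows(seqs, k))
  scodes <- encode_kmers(pat, ab, wildcard)
  wcodes <- encode_kmers(win$kmer, ab)
  res <- cpp_match_records(scodes, wcodes, win$seq_index, k, as.integer(m),
                           length(ab), nrow(seqs), as.integer(q), FALSE)
  keep <- res$counts >= q
  nw <- vapply(strsplit(pat[keep], "", fixed = TRUE),
               function(ch) sum(ch == wildcard), 1L)
  out <- stem_set_tibble(pat[keep], nw, wildcard)
  out$n_records_matched <- res$counts[keep]
  out
}

#' Expand surviving stems and verify explicit motifs
#'
#' Instantiates every surviving stem over the alphabet, deduplicates, and
#' keeps the k-mers within Hamming distance `m` of at least `q` records — the
#' explicit motif set of the formal problem definition.
#'
#' @param survivors A `stem_set` or character vector of patterns.
#' @param seqs A `seq_set`.
#' @param m Maximum mismatches.
#' @param q Quorum.
#' @param alphabet Symbols; the sequence-set alphabet when `NULL`.
#' @param cap Capacity bound on the number of instantiations.
#' @param wildcard Wildcard character.
#' @return Character vector of motif k-mers (sorted) with attribute
#'   `n_records` (records matched per motif).
#' @export
expand_and_verify <- function(survivors, seqs, m, q, alphabet = NULL,
                              cap = 2^26, wildcard = WILDCARD) {
  pat <- if (is.character(survivors)) survivors else survivors$pattern
  if (!is.character(survivors) && !is.null(attr(survivors, "wildcard"))) {
    wildcard <- attr(survivors, "wildcard")
  }
  if (is.null(alphabet)) alphabet <- alphabet(seqs)
  sigma <- length(alphabet)
  if (length(pat) == 0) {
    out <- character(0)
    attr(out, "n_records") <- integer(0)
    return(out)
  }
  k <- nchar(pat[1])
  nw <- vapply(strsplit(pat, "", fixed = TRUE),
               function(ch) sum(ch == wildcard), 1L)
  check_expansion_cap(nw, sigma, k, cap)
  win <- suppressWarnings(extract_windows(seqs, k))
  ev <- cpp_expand_verify(encode_kmers(pat, alphabet, wildcard),
                          encode_kmers(win$kmer, alphabet), win$seq_index,
                          k, as.integer(m), sigma, nrow(seqs), as.integer(q))
  out <- decode_kmers(ev$motifs, k, alphabet)
  attr(out, "n_records") <- ev$n_records
  out
}

check_expansion_cap <- function(n_wildcards, sigma, k, cap) {
  total <- sum(as.numeric(sigma)^n_wildcards)
  effective <- min(total, pow_or_inf(sigma, k))
  if (effective > cap) {
    abort_capacity(sprintf(
      "expansion of %.3g instantiations exceeds the cap of %.3g; rerun with expand = FALSE (--no-expand) or raise expansion_cap",
      effective, cap))
  }
  invisible(effective)
}

#' Exact motif search with wildcard stems
#'
#' Runs the full pipeline: extract k-mer windows; select candidate instances
#' within Hamming distance `2m` of at least `quorum` records by counting-sort
#' rounds; build the candidate stem set over pairs of selected k-mers; prune
#' stems failing the motif property; optionally remove subsumed stems from
#' the report; optionally expand survivors into explicit, individually
#' verified motif k-mers; and locate the best site per record for every
#' reported pattern. Deterministic for fixed input.
#'
#' Two output levels are produced because they answer different questions:
#' surviving stems (patterns with wildcards that match at least `quorum`
#' records with at most `m` masked mismatches) and, when `expand` is active,
#' explicit motif k-mers each verified to lie within `m` of at least `quorum`
#' records — the motif set of the formal problem statement.
#'
#' @param seqs A `seq_set`.
#' @param k Motif length.
#' @param m Maximum mismatches (`0 <= m < k`).
#' @param quorum Number of records a motif must match; defaults to all
#'   records.
#' @param pair_policy `"all"` unordered pairs of selected k-mers (default) or
#'   `"cross-record"` pairs only.
#' @param expand `"auto"` (expand when the instantiation total fits the cap,
#'   otherwise warn and skip), `TRUE`/"always" (error above the cap) or
#'   `FALSE`/"never".
#' @param minimize Remove subsumed stems from the reported stem set.
#' @param expansion_cap Capacity bound for expansion.
#' @param stem_report_limit Materialize the surviving-stem tibble only up to
#'   this many stems (the count is always reported in the stage statistics).
#' @param all_hits Report all minimal-distance sites per record, not only the
#'   leftmost.
#' @param pair_budget Warn when the k-mer pair count exceeds this.
#' @param wildcard Wildcard display character; default `n` for nucleotide
#'   alphabets, `x` otherwise.
#' @return A `motif_result`: list with `stems` (tibble or `NULL`), `motifs`
#'   (character), `sites` (tibble), `stats` (one-row tibble of stage sizes),
#'   `params`, `alphabet`.
#' @examples
#' s <- seq_set(c("r1", "r2"), c("AACGTT", "TACGTA"))
#' find_motifs(s, k = 3, m = 0, quorum = 2)
#' @export
find_motifs <- function(seqs, k, m, quorum = NULL,
                        pair_policy = c("all", "cross-record"),
                        expand = "auto", minimize = FALSE,
                        expansion_cap = 2^26, stem_report_limit = 2e5,
                        all_hits = FALSE, pair_budget = 2e8,
                        wildcard = NULL) {
  pair_policy <- match.arg(pair_policy)
  if (isTRUE(expand)) expand <- "always"
  if (isFALSE(expand)) expand <- "never"
  expand <- match.arg(expand, c("auto", "always", "never"))
  N <- nrow(seqs)
  ab <- alphabet(seqs)
  sigma <- length(ab)
  if (is.null(wildcard)) {
    wildcard <- if (all(c("A", "C", "G", "T") %in% ab) && sigma <= 5) "n" else "x"
  }
  if (wildcard %in% ab) abort_config("wildcard display character is a member of the alphabet")
  if (k < 1) abort_usage("k must be at least 1")
  if (m < 0 || m >= k) abort_usage(sprintf("m must satisfy 0 <= m < k (got k = %d, m = %d)", k, m))
  check_k_limit(k)
  q <- if (is.null(quorum)) N else as.integer(quorum)
  if (q < 1 || q > N) abort_usage(sprintf("quorum must satisfy 1 <= q <= N = %d", N))
  if (2 * m >= k) {
    warn(sprintf("degenerate parameters: 2m = %d >= k = %d; selection cannot discard anything", 2 * m, k))
  }

  win <- extract_windows(seqs, k)
  n_windows <- nrow(win)
  params <- list(k = k, m = m, quorum = q, pair_policy = pair_policy,
                 expand = expand, minimize = minimize,
                 expansion_cap = expansion_cap, wildcard = wildcard)

  wcodes <- encode_kmers(win$kmer, ab)
  sel <- cpp_match_records(wcodes, wcodes, win$seq_index, k,
                           as.integer(2 * m), sigma, N, q, FALSE)
  selected <- sel$counts >= q
  n_selected <- sum(selected)

  if (n_selected == 0) {
    warn("no k-mer is within 2m of the quorum; no motif can exist")
    return(new_motif_result(
      stems = stem_set_tibble(character(0), integer(0), wildcard),
      motifs = character(0), motif_records = integer(0),
      sites = empty_sites(), params = params, alphabet = ab,
      stats = tibble(n_windows = n_windows, n_skipped = attr(win, "n_skipped"),
                     n_selected = 0L, n_distinct_selected = 0L,
                     n_pairs = 0, n_close_pairs = 0, n_candidates = 0,
                     n_survivors = 0, n_motifs = 0L)))
  }

  selk <- win$kmer[selected]
  selrec <- win$seq_index[selected]
  ukm <- unique(selk)
  kd <- dplyr::distinct(tibble(kmer = selk, rec = selrec))
  nrec_per <- tapply(kd$rec, kd$kmer, function(r) length(r))
  own1 <- tapply(kd$rec, kd$kmer, function(r) r[1])
  own_rec <- ifelse(nrec_per[ukm] > 1, -1L, as.integer(own1[ukm]))

  if (as.numeric(length(ukm))^2 > pair_budget) {
    warn(sprintf("forming ~%.3g k-mer pairs; this may be slow",
                 as.numeric(length(ukm))^2 / 2))
  }
  ps <- cpp_pair_stems(encode_kmers(ukm, ab), k, sigma, as.integer(m),
                       as.integer(own_rec), pair_policy == "cross-record")
  n_candidates <- length(ps$n_wildcards)

  pr <- cpp_match_records(ps$stems, wcodes, win$seq_index, k, as.integer(m),
                          sigma, N, q, FALSE)
  surv <- pr$counts >= q
  n_survivors <- sum(surv)
  surv_nw <- ps$n_wildcards[surv]

  stems_tbl <- NULL
  if (n_survivors <= stem_report_limit) {
    spat <- decode_kmers(cpp_subset_rows(ps$stems, k, which(surv) - 1L), k, ab, wildcard)
    stems_tbl <- stem_set_tibble(spat, surv_nw, wildcard)
    stems_tbl$n_records_matched <- pr$counts[surv]
    if (minimize) {
      mm <- minimize_stems(stems_tbl, wildcard)
      mm$n_records_matched <- stems_tbl$n_records_matched[match(mm$pattern, stems_tbl$pattern)]
      stems_tbl <- mm
    }
  }

  motifs <- character(0)
  motif_records <- integer(0)
  do_expand <- expand != "never"
  # The instantiation cap constrains the enumerating expansion path (small
  # alphabets, where the k-mer space fits a bitmap); the large-alphabet path
  # assigns wildcards depth-first with quorum pruning and materializes only
  # verified motifs, so no pre-expansion bound is needed.
  enumerating <- k * log2(sigma) <= 31
  if (do_expand && enumerating) {
    eff <- tryCatch(check_expansion_cap(surv_nw, sigma, k, expansion_cap),
                    stemotif_capacity_error = function(e) e)
    if (rlang::is_condition(eff)) {
      if (expand == "always") rlang::cnd_signal(eff)
      warn(paste0("expansion skipped: ", rlang::cnd_message(eff)))
      do_expand <- FALSE
    }
  }
  if (do_expand && n_survivors > 0) {
    surv_raw <- cpp_subset_rows(ps$stems, k, which(surv) - 1L)
    # Verification against the selected occurrences is exact: any window
    # witnessing a record of a quorum-passing motif lies within 2m of every
    # matched record and is therefore itself selected.
    sel_idx <- which(selected)
    wsel <- cpp_subset_rows(wcodes, k, sel_idx - 1L)
    ev <- cpp_expand_verify(surv_raw, wsel, win$seq_index[sel_idx], k,
                            as.integer(m), sigma, N, q)
    motifs <- decode_kmers(ev$motifs, k, ab)
    motif_records <- ev$n_records
  }

  reported <- if (do_expand) motifs else if (!is.null(stems_tbl)) stems_tbl$pattern else character(0)
  sites <- locate_sites_many(reported, seqs, m, all_hits = all_hits,
                             wildcard = wildcard)

  new_motif_result(
    stems = stems_tbl, motifs = motifs, motif_records = motif_records,
    sites = sites, params = params, alphabet = ab,
    stats = tibble(n_windows = n_windows, n_skipped = attr(win, "n_skipped"),
                   n_selected = n_selected,
                   n_distinct_selected = length(ukm),
                   n_pairs = ps$n_pairs, n_close_pairs = ps$n_close_pairs,
                   n_candidates = n_candidates, n_survivors = n_survivors,
                   n_motifs = length(motifs)))
}

new_motif_result <- function(stems, motifs, motif_records, sites, params,
                             alphabet, stats) {
  structure(list(stems = stems, motifs = motifs,
                 motif_records = motif_records, sites = sites,
                 stats = stats, params = params, alphabet = alphabet),
            class = "motif_result")
}

empty_sites <- function() {
  tibble(pattern = character(0), seq_index = integer(0), seq_id = character(0),
         offset = integer(0), window = character(0), distance = integer(0),
         primary = logical(0))
}

#' Locate the best-matching sites of a pattern in every record
#'
#' Per record, the minimal-distance window(s) with distance at most `m`; the
#' primary hit is the leftmost among the minimal ones. Records without a
#' qualifying window yield no hit.
#'
#' @param pattern A stem (wildcards allowed) or explicit k-mer.
#' @param seqs A `seq_set`.
#' @param m Maximum mismatches.
#' @param all_hits Keep all minimal-distance hits, not only the leftmost.
#' @param wildcard Wildcard character used in `pattern`.
#' @return Tibble with columns `pattern`, `seq_index`, `seq_id`, `offset`,
#'   `window`, `distance`, `primary`.
#' @export
locate_sites <- function(pattern, seqs, m, all_hits = FALSE,
                         wildcard = WILDCARD) {
  locate_sites_many(pattern, seqs, m, all_hits = all_hits, wildcard = wildcard)
}

locate_sites_many <- function(patterns, seqs, m, all_hits = FALSE,
                              wildcard = WILDCARD) {
  if (length(patterns) == 0) return(empty_sites())
  ab <- alphabet(seqs)
  k <- nchar(patterns[1])
  win <- suppressWarnings(extract_windows(seqs, k))
  sigma <- length(ab)
  wmat <- matrix(as.integer(encode_kmers(win$kmer, ab)), nrow = k)
  pmat <- matrix(as.integer(encode_kmers(patterns, ab, wildcard)), nrow = k)
  out <- vector("list", length(patterns))
  for (pi in seq_along(patterns)) {
    pc <- pmat[, pi]
    live <- pc != sigma
    d <- colSums(wmat[live, , drop = FALSE] != pc[live])
    hit <- tibble(pattern = patterns[pi], seq_index = win$seq_index,
                  seq_id = seqs$id[win$seq_index + 1L], offset = win$offset,
                  window = win$kmer, distance = as.integer(d))
    hit <- hit[hit$distance <= m, , drop = FALSE]
    if (nrow(hit) == 0) next
    hit <- hit %>%
      group_by(seq_index) %>%
      filter(distance == min(distance)) %>%
      mutate(primary = offset == min(offset)) %>%
      ungroup()
    if (!all_hits) hit <- hit[hit$primary, , drop = FALSE]
    out[[pi]] <- hit
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) empty_sites() else res
}

#' Instance-majority consensus of aligned site windows
#'
#' Per column: the unanimous symbol, or a bracket group of the distinct
#' observed symbols in sorted order (e.g. `A[CT]G`).
#'
#' @param windows Character vector of equal-length site windows.
#' @return A single pattern string.
#' @examples
#' build_consensus(c("ACG", "ATG"))
#' @export
build_consensus <- function(windows) {
  if (length(windows) == 0) abort_usage("consensus of an empty window set is undefined")
  k <- nchar(windows[1])
  if (any(nchar(windows) != k)) abort_usage("all windows must share one length")
  cm <- char_matrix(windows, k)
  cols <- vapply(seq_len(k), function(i) {
    u <- sort(unique(cm[i, ]))
    if (length(u) == 1) u else paste0("[", paste(u, collapse = ""), "]")
  }, "")
  paste(cols, collapse = "")
}

#' @export
print.motif_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf("Motif search result (k = %d, m = %d, quorum = %d)\n",
              x$params$k, x$params$m, x$params$quorum))
  cat(sprintf("  windows: %s   selected: %s   distinct: %s\n",
              format(s$n_windows), format(s$n_selected),
              format(s$n_distinct_selected)))
  cat(sprintf("  candidate stems: %s   survivors: %s\n",
              format(s$n_candidates), format(s$n_survivors)))
  if (length(x$motifs) > 0) {
    cat(sprintf("  explicit motifs: %d\n", length(x$motifs)))
    show <- utils::head(x$motifs, 10)
    cat("   ", paste(show, collapse = " "), if (length(x$motifs) > 10) "..." else "", "\n")
  } else {
    cat(sprintf("  explicit motifs: %d\n", s$n_motifs))
  }
  invisible(x)
}

#' Tidy the per-pattern motif report
#'
#' One row per reported pattern: wildcards, records matched, primary-site
#' mismatch total and the bracket consensus of its primary site windows.
#'
#' @param x A `motif_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.motif_result <- function(x, ...) {
  reported <- if (length(x$motifs) > 0) {
    tibble(pattern = x$motifs, n_wildcards = 0L,
           n_records_matched = as.integer(x$motif_records))
  } else if (!is.null(x$stems)) {
    tibble(pattern = x$stems$pattern, n_wildcards = x$stems$n_wildcards,
           n_records_matched = x$stems$n_records_matched)
  } else {
    tibble(pattern = character(0), n_wildcards = integer(0),
           n_records_matched = integer(0))
  }
  prim <- x$sites[x$sites$primary, , drop = FALSE]
  agg <- prim %>%
    group_by(pattern) %>%
    summarise(n_sites = n(),
              total_mismatches = sum(distance),
              consensus = build_consensus(window),
              .groups = "drop")
  out <- left_join(reported, agg, by = "pattern")
  out$n_sites[is.na(out$n_sites)] <- 0L
  out
}

#' One-row stage-statistics summary
#' @param x A `motif_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.motif_result <- function(x, ...) x$stats

#' Site map of a motif search result
#'
#' Draws each reported site as a horizontal segment along its record, colored
#' by mismatch count.
#'
#' @param object A `motif_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_result <- function(object, ...) {
  sites <- object$sites[object$sites$primary, , drop = FALSE]
  k <- object$params$k
  ggplot2::ggplot(sites,
                  ggplot2::aes(x = offset, xend = offset + k,
                               y = seq_id, yend = seq_id,
                               colour = factor(distance))) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "offset (0-based)", y = NULL, colour = "mismatches") +
    ggplot2::theme_minimal()
}

#' @exportS3Method graphics::plot
plot.motif_result <- function(x, ...) print(autoplot.motif_result(x, ...))

#' Write the motif report as TSV
#'
#' Frozen columns: `pattern`, `n_wildcards`, `n_records_matched`,
#' `total_mismatches_of_primary_sites`, `sites` (semicolon-joined
#' `seq_id:offset:distance` of primary sites, 0-based).
#'
#' @param x A `motif_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_report <- function(x, path) {
  td <- tidy(x)
  prim <- x$sites[x$sites$primary, , drop = FALSE]
  sstr <- prim %>%
    group_by(pattern) %>%
    summarise(sites = paste(sprintf("%s:%d:%d", seq_id, offset, distance),
                            collapse = ";"),
              .groups = "drop")
  out <- left_join(td, sstr, by = "pattern")
  out <- tibble(pattern = out$pattern, n_wildcards = out$n_wildcards,
                n_records_matched = out$n_records_matched,
                total_mismatches_of_primary_sites = out$total_mismatches,
                sites = out$sites)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write sites as 6-column BED (0-based half-open)
#' @param x A `motif_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(x, path) {
  s <- x$sites[x$sites$primary, , drop = FALSE]
  bed <- tibble(chrom = s$seq_id, start = s$offset,
                end = s$offset + x$params$k, name = s$pattern,
                score = s$distance, strand = "+")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write explicit motifs as FASTA
#' @param x A `motif_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs_fasta <- function(x, path) {
  ss <- Biostrings::BStringSet(x$motifs)
  names(ss) <- sprintf("motif_%d", seq_along(x$motifs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
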