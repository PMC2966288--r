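#' Mutate a consensus k-mer into a planted instance
#'
#' Picks `s` distinct positions (`s = m` in `"exact"` mode, uniform on
#' `0..m` in `"uniform"` mode) and replaces the symbol at each with a uniform
#' draw from the other alphabet symbols, so the instance lies at Hamming
#' distance exactly `s` from the consensus. Uses the current RNG state.
#'
#' @param consensus A k-mer.
#' @param m Maximum substitutions (`m < k`).
#' @param mode `"exact"` (always `m` substitutions) or `"uniform"` (`0..m`).
#' @param alphabet Character vector of symbols.
#' @return List with `instance` (k-mer) and `positions` (0-based sorted
#'   substituted positions).
#' @export
mutate_consensus <- function(consensus, m, mode = c("exact", "uniform"),
                             alphabet) {
  mode <- match.arg(mode)
  k <- nchar(consensus)
  if (m >= k) abort_usage("m must be smaller than k")
  s <- if (mode == "exact") m else sample(0:m, 1)
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  pos <- if (s > 0) sort(sample(k, s)) else integer(0)
  for (p in pos) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  }
  list(instance = paste(chars, collapse = ""), positions = pos - 1L)
}

default_alphabet <- function(sigma) {
  if (sigma == 4) return(c("A", "C", "G", "T"))
  if (sigma == 20) return(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  pool <- c(LETTERS, letters, as.character(0:9))
  if (sigma > length(pool)) abort_usage("sigma too large for the built-in symbol pool")
  pool[seq_len(sigma)]
}

#' Generate a planted-motif benchmark instance
#'
#' The standard challenge protocol: `N` iid uniform random strings of length
#' `n` over an alphabet of `sigma` symbols, each carrying one implanted copy
#' of a hidden consensus k-mer mutated by `m` substitutions (exactly `m` in
#' `"exact"` mode, the convention of the hard benchmark instances; up to `m`
#' in `"uniform"` mode) at a uniform random offset. Deterministic for a fixed
#' seed (R's default Mersenne-Twister RNG); the truth fields record
#' everything needed to verify recovery.
#'
#' @param N Number of strings.
#' @param n String length.
#' @param sigma Alphabet size (4 = DNA `ACGT`, 20 = amino acids, otherwise
#'   letters then digits).
#' @param k Motif length.
#' @param m Substitutions per implant.
#' @param mode `"exact"` or `"uniform"`.
#' @param seed Integer seed.
#' @return A `planted_instance`: list with `sequences` (a [seq_set()]),
#'   `consensus`, `truth` (tibble: `seq_id`, `offset`, `instance`,
#'   `n_substitutions`, `substituted_positions` list-column) and the
#'   parameters.
#' @examples
#' pi <- plant_instance(N = 5, n = 50, sigma = 4, k = 9, m = 2, seed = 1)
#' pi$consensus
#' @export
plant_instance <- function(N, n, sigma, k, m, mode = c("exact", "uniform"),
                           seed = 1) {
  mode <- match.arg(mode)
  if (k > n) abort_usage("k must not exceed n")
  if (sigma < 2) abort_usage("sigma must be at least 2")
  if (m >= k) abort_usage("m must be smaller than k")
  ab <- default_alphabet(sigma)
  withr::with_seed(as.integer(seed), {
    consensus <- paste(sample(ab, k, replace = TRUE), collapse = "")
    rows <- vector("list", N)
    seqs <- character(N)
    for (i in seq_len(N)) {
      bg <- sample(ab, n, replace = TRUE)
      mut <- mutate_consensus(consensus, m, mode, ab)
      off <- sample(0:(n - k), 1)
      bg[(off + 1):(off + k)] <- strsplit(mut$instance, "", fixed = TRUE)[[1]]
      seqs[i] <- paste(bg, collapse = "")
      rows[[i]] <- tibble(seq_id = sprintf("seq%02d", i), offset = off,
                          instance = mut$instance,
                          n_substitutions = length(mut$positions),
                          substituted_positions = list(mut$positions))
    }
    truth <- bind_rows(rows)
    structure(list(sequences = seq_set(truth$seq_id, seqs, alphabet = ab),
                   consensus = consensus, truth = truth,
                   k = k, m = m, sigma = sigma, N = N, n = n,
                   mode = mode, seed = as.integer(seed)),
              class = "planted_instance")
  })
}

#' @export
print.planted_instance <- function(x, ...) {
  cat(sprintf("Planted (%d,%d) instance: N = %d strings of length %d over %d symbols (seed %d)\n",
              x$k, x$m, x$N, x$n, x$sigma, x$seed))
  cat(sprintf("  consensus: %s (%s mode)\n", x$consensus, x$mode))
  invisible(x)
}

#' Write a planted instance to FASTA + truth TSV
#'
#' The truth TSV carries a header comment line recording consensus, k, m,
#' sigma, mode and seed, then one row per record: `seq_id`, `offset`,
#' `instance`, `n_substitutions`, `substituted_positions` (comma-joined,
#' 0-based).
#'
#' @param x A `planted_instance`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_planted <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "seqs.fasta")
  tsv <- file.path(dir, "truth.tsv")
  write_fasta(x$sequences, fa)
  hdr <- sprintf("# consensus=%s k=%d m=%d sigma=%d mode=%s seed=%d",
                 x$consensus, x$k, x$m, x$sigma, x$mode, x$seed)
  body <- x$truth %>%
    mutate(substituted_positions =
             map_chr(substituted_positions, paste, collapse = ","))
  writeLines(c(hdr, paste(colnames(body), collapse = "\t"),
               do.call(paste, c(as.list(body), list(sep = "\t")))), tsv)
  invisible(c(fasta = fa, truth = tsv))
}
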