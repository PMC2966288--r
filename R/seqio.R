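#' Construct a sequence set
#'
#' A sequence set is a tibble with columns `id` and `seq` plus an `alphabet`
#' attribute (the ordered set of valid residue symbols). Residues outside the
#' alphabet are retained but treated as invalid when k-mer windows are
#' extracted.
#'
#' @param id Character vector of record identifiers (unique).
#' @param seq Character vector of residues, same length as `id`.
#' @param alphabet Optional character vector of single-symbol strings. When
#'   `NULL`, the sorted distinct residues observed across all records.
#' @return A `seq_set` tibble with columns `id`, `seq`.
#' @examples
#' seq_set(c("a", "b"), c("ACGT", "ACGG"))
#' @export
seq_set <- function(id, seq, alphabet = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) abort_usage("id and seq must have equal length")
  if (length(seq) < 1) abort_usage("a sequence set needs at least one record")
  if (any(!nzchar(seq))) {
    abort_format(sprintf("empty sequence for record '%s'",
                         id[which(!nzchar(seq))[1]]))
  }
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    abort_format(sprintf("duplicate record id '%s'", dup[1]))
  }
  out <- tibble(id = id, seq = seq)
  class(out) <- c("seq_set", class(out))
  attr(out, "alphabet") <- validate_alphabet(alphabet, seq)
  out
}

validate_alphabet <- function(alphabet, seq = NULL) {
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(strsplit(seq, "", fixed = TRUE))))
  }
  alphabet <- as.character(alphabet)
  if (any(nchar(alphabet) != 1)) abort_config("alphabet symbols must be single characters")
  if (anyDuplicated(alphabet)) abort_config("alphabet symbols must be distinct")
  if (WILDCARD %in% alphabet) {
    abort_config(sprintf("the wildcard display character '%s' cannot be an alphabet member", WILDCARD))
  }
  if (length(alphabet) < 2) abort_config("alphabet must contain at least 2 symbols")
  alphabet
}

#' Get the alphabet of a sequence set
#' @param x A `seq_set`.
#' @return Character vector of symbols.
#' @export
alphabet <- function(x) attr(x, "alphabet")

#' Read sequences from a FASTA file
#'
#' Records keep file order; residues are uppercased with line breaks and
#' whitespace removed; the record id is the header token up to the first
#' whitespace. The alphabet is inferred as the sorted distinct residues
#' observed (override with [infer_alphabet()]).
#'
#' @param path Path to a FASTA file.
#' @return A `seq_set` tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seq_set(ids, as.character(ss))
}

#' Write a sequence set to a FASTA file
#' @param seqs A `seq_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs$seq)
  names(ss) <- seqs$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Declare or re-infer the alphabet of a sequence set
#'
#' With `declared` given, it becomes the alphabet (residues outside it stay in
#' the records but are invalid for windowing); otherwise the alphabet is the
#' sorted distinct residues observed.
#'
#' @param seqs A `seq_set`.
#' @param declared Optional character vector of symbols (single characters or
#'   one string, e.g. `"ACGT"`).
#' @return The `seq_set` with its alphabet set.
#' @export
infer_alphabet <- function(seqs, declared = NULL) {
  if (!is.null(declared) && length(declared) == 1 && nchar(declared[1]) > 1) {
    declared <- strsplit(declared, "", fixed = TRUE)[[1]]
  }
  attr(seqs, "alphabet") <- validate_alphabet(declared, seqs$seq)
  seqs
}

#' Extract all k-mer windows with provenance
#'
#' Yields, for each record of length `n_i`, the windows at offsets
#' `0..n_i - k` (0-based). Windows containing any symbol outside the alphabet
#' are omitted and counted in a skip log (emitted as a warning).
#'
#' @param seqs A `seq_set`.
#' @param k Window length.
#' @return Tibble with columns `kmer`, `seq_index` (0-based record index) and
#'   `offset` (0-based start), plus attribute `n_skipped`.
#' @export
extract_windows <- function(seqs, k) {
  ab <- alphabet(seqs)
  lens <- nchar(seqs$seq)
  if (k < 1) abort_usage("k must be at least 1")
  if (all(k > lens)) abort_input(sprintf("k = %d exceeds every record length", k))
  check_k_limit(k)

  n_skipped <- 0L
  out <- vector("list", nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    n_i <- lens[i]
    if (k > n_i) next
    offs <- 0:(n_i - k)
    kmers <- substring(seqs$seq[i], offs + 1L, offs + k)
    bad <- is.na(match(strsplit(seqs$seq[i], "", fixed = TRUE)[[1]], ab))
    if (any(bad)) {
      cb <- cumsum(bad)
      win_bad <- (cb[offs + k] - c(0L, cb)[offs + 1L]) > 0L
      n_skipped <- n_skipped + sum(win_bad)
      offs <- offs[!win_bad]
      kmers <- kmers[!win_bad]
    }
    out[[i]] <- tibble(kmer = kmers, seq_index = i - 1L, offset = offs)
  }
  res <- bind_rows(out)
  if (n_skipped > 0) {
    warn(sprintf("skipped %d windows containing symbols outside the alphabet", n_skipped))
  }
  attr(res, "n_skipped") <- n_skipped
  res
}
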