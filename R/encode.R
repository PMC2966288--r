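# Internal symbol-code plumbing. Patterns are exchanged with the C++ engines
# as raw vectors of per-position codes: 0..sigma-1 for alphabet symbols (in
# alphabet order) and sigma for the wildcard.

WILDCARD <- "?"

# Split equal-length strings into a character matrix (k rows, n cols).
char_matrix <- function(x, k) {
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE), nrow = k)
}

encode_kmers <- function(x, alphabet, wildcard = WILDCARD, what = "k-mer") {
  if (length(x) == 0) return(raw(0))
  k <- nchar(x[1])
  if (any(nchar(x) != k)) abort_usage(sprintf("all %ss must share one length", what))
  codes <- match(char_matrix(x, k), c(alphabet, wildcard)) - 1L
  if (anyNA(codes)) {
    bad <- setdiff(unique(unlist(strsplit(x, "", fixed = TRUE))),
                   c(alphabet, wildcard))
    abort_usage(sprintf("%s contains symbols outside the alphabet: %s",
                        what, paste(bad, collapse = ", ")))
  }
  as.raw(codes)
}

decode_kmers <- function(r, k, alphabet, wildcard = WILDCARD) {
  if (length(r) == 0) return(character(0))
  syms <- c(alphabet, wildcard)[as.integer(r) + 1L]
  dim(syms) <- c(k, length(r) / k)
  do.call(paste0, lapply(seq_len(k), function(i) syms[i, ]))
}

check_k_limit <- function(k) {
  if (k > 48) abort_usage("motif lengths above 48 are not supported")
}

# log(sigma^k), guarded; returns Inf-safe double of sigma^k or Inf.
pow_or_inf <- function(sigma, k) {
  v <- k * log(sigma)
  if (v > log(.Machine$double.xmax)) Inf else exp(v)
}
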