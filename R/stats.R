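#' Probability that two random k-mers lie within distance d
#'
#' For two iid uniform k-mers over `sigma` symbols, the probability of at
#' most `d` mismatches:
#' `sum_{j=0..d} C(k,j) ((sigma-1)/sigma)^j (1/sigma)^(k-j)`.
#'
#' @param k Word length.
#' @param d Maximum mismatches (`0 <= d <= k`).
#' @param sigma Alphabet size.
#' @return Probability in `[0, 1]`.
#' @examples
#' pairwise_match_probability(13, 8, 20)
#' @export
pairwise_match_probability <- function(k, d, sigma) {
  if (d < 0 || d > k) abort_usage("d must satisfy 0 <= d <= k")
  if (sigma < 2) abort_usage("sigma must be at least 2")
  j <- 0:d
  sum(exp(lchoose(k, j) + j * log(sigma - 1) - k * log(sigma)))
}

#' Expected number of chance candidate k-mers
#'
#' Expected count of k-mers over the whole space `sigma^k` that, by chance,
#' lie within Hamming distance `2m` of at least one window in each of `N` iid
#' uniform strings of length `n`:
#' `sigma^k (1 - (1 - p)^t)^N` with `p` the pairwise probability at distance
#' `2m` and `t` the per-string window count. Evaluated in log space. The
#' window count convention defaults to `t = n`; `"n-k+1"` uses the exact
#' number of windows.
#'
#' @param k Motif length.
#' @param m Maximum mismatches (the distance used is `2m`).
#' @param n String length.
#' @param N Number of strings.
#' @param sigma Alphabet size.
#' @param windows Window-count convention, `"n"` (default) or `"n-k+1"`.
#' @return Expected count (non-negative real).
#' @examples
#' expected_background_candidates(13, 4, 600, 20, 20)  # about 8
#' @export
expected_background_candidates <- function(k, m, n, N, sigma,
                                           windows = c("n", "n-k+1")) {
  windows <- match.arg(windows)
  if (2 * m > k) abort_usage("2m must not exceed k")
  if (n < k || N < 1) abort_usage("need n >= k and N >= 1")
  p <- pairwise_match_probability(k, 2 * m, sigma)
  t <- if (windows == "n") n else n - k + 1
  if (p >= 1) return(pow_or_inf(sigma, k))
  # log of (1 - (1-p)^t), stable for small p
  lP <- log(-expm1(t * log1p(-p)))
  exp(k * log(sigma) + N * lP)
}

#' Expected size of the selected candidate-instance set
#'
#' With `t` implanted motif instances among `n N` input k-mers, the expected
#' number selected is
#' `E = t + n N (1 - (1 - p)^t) + E_background`,
#' where `p` is the pairwise probability at distance `2m`: the implants
#' themselves, the background k-mers dragged in by their closeness to an
#' implant, and the pure-chance candidates.
#'
#' @param t Number of implanted instances.
#' @param k,m,n,N,sigma As in [expected_background_candidates()].
#' @param windows Window-count convention for the background term.
#' @return Expected selected-set size.
#' @examples
#' expected_selected_size(1, 13, 4, 600, 20, 20)  # about 12
#' @export
expected_selected_size <- function(t, k, m, n, N, sigma,
                                   windows = c("n", "n-k+1")) {
  if (t < 0) abort_usage("t must be non-negative")
  p <- pairwise_match_probability(k, 2 * m, sigma)
  t + n * N * (1 - (1 - p)^t) +
    expected_background_candidates(k, m, n, N, sigma, windows)
}

#' Analytic estimate report
#'
#' Bundles the neighborhood size, the pairwise probability at `2m`, the
#' expected chance background and the expected selected-set size for one
#' parameter setting.
#'
#' @param k,m,n,N,sigma Problem parameters.
#' @param t Implanted instances (for the selected-size estimate).
#' @param windows Window-count convention.
#' @return One-row tibble with columns `v_neighborhood`, `p_pair`,
#'   `expected_background`, `expected_selected`.
#' @export
estimate_report <- function(k, m, n, N, sigma, t = 1,
                            windows = c("n", "n-k+1")) {
  windows <- match.arg(windows)
  tibble(
    k = k, m = m, n = n, N = N, sigma = sigma, t = t,
    v_neighborhood = neighborhood_size(k, m, sigma),
    p_pair = pairwise_match_probability(k, 2 * m, sigma),
    expected_background = expected_background_candidates(k, m, n, N, sigma, windows),
    expected_selected = expected_selected_size(t, k, m, n, N, sigma, windows))
}

#' Site-level performance coefficient
#'
#' Nucleotide-level Jaccard agreement between known and predicted sites:
#' `100 |K ∩ P| / |K ∪ P|` over (record, position) pairs, with sites given
#' as 0-based half-open intervals.
#'
#' @param known,predicted Tibbles/data frames with columns `record`, `start`,
#'   `end` (0-based half-open).
#' @return Percentage in `[0, 100]`.
#' @examples
#' performance_coefficient(
#'   data.frame(record = "r1", start = 0, end = 10),
#'   data.frame(record = "r1", start = 5, end = 15))  # 33.33
#' @export
performance_coefficient <- function(known, predicted) {
  pos_set <- function(x) {
    if (nrow(x) == 0) return(character(0))
    if (any(x$end <= x$start)) abort_usage("intervals must satisfy start < end")
    unique(unlist(Map(function(r, s, e) paste0(r, ":", s:(e - 1)),
                      x$record, x$start, x$end)))
  }
  K <- pos_set(known)
  P <- pos_set(predicted)
  u <- union(K, P)
  if (length(u) == 0) abort_usage("performance coefficient of two empty site sets is undefined")
  100 * length(intersect(K, P)) / length(u)
}
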