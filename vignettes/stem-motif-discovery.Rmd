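---
title: "Exact motif discovery with wildcard stems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact motif discovery with wildcard stems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemotif)
```

## The problem

Given `N` sequences over an alphabet of `sigma` symbols, the planted
(k, m)-motif problem asks for every k-mer `x` whose Hamming distance to each
of at least `q` sequences — meaning the best distance over all length-k
windows of that sequence — is at most `m`. For transcription-factor binding
sites a typical instance is `k = 9..20`, `m = 2..7` over the DNA alphabet;
for protein motifs the alphabet has 20 symbols and instances such as
(13, 4) or (15, 7) arise. Exhaustive algorithms that enumerate explicit
mismatch neighborhoods pay a factor of
`V(k, m) = sum_i C(k, i) (sigma - 1)^i`, which grows rapidly with the
alphabet size; this package implements an exact search whose combinatorial
core is independent of `sigma`.

## The three-stage search

`find_motifs()` runs three stages, each exposed as its own function.

**1. Selection** (`select_candidates()`). Two windows can be instances of a
common motif only if they disagree in at most `2m` positions (triangle
inequality through the motif). The selection stage therefore keeps exactly
the windows that are within distance `2m` of at least `q` records. It does
so with `C(k, 2m)` counting-sort rounds: each round deletes one subset of
`2m` positions and groups equal reductions, so two windows share a group in
some round precisely when their mismatches fit inside the deleted subset.
A window's match mask accumulates records across rounds — a record may be
witnessed in any round, not necessarily the same one for all records — and
the window's own record always counts (distance 0). The expected size of
the selected set `I` is orders of magnitude below the input size `n N` for
large alphabets (see the estimators below), which is what makes the
downstream stages cheap in the regimes where neighborhood enumeration is
most expensive.

**2. Candidate stems** (`build_candidate_set()`, `generate_stems()`). For
every pair of distinct selected k-mers at distance `d <= 2m` (and every
self-pair), the pairwise neighborhood intersection — the k-mers within `m`
of both — is represented as a set of *stems*: length-k patterns over the
alphabet plus a wildcard. With `D` the mismatch region of the pair
(`d = |D|`), the enumeration chooses `i` positions of `D` set to the second
k-mer's symbol (`max(0, d - m) <= i <= min(d, m)`), `j1` wildcards in the
remaining mismatch positions, and `j2` wildcards in the match region subject
to `j2 <= m - max(i + j1, d - i)`; every other position carries the first
k-mer's symbol. The two bounds are exactly the worst-case instantiation
distances to the two parents, so every instantiation lies in the
intersection, and the union of instantiations covers it exactly — a property
the test suite enforces against an exhaustive enumeration oracle on
hundreds of random pairs. The number of stems,
`count_stems(k, d, m)`, depends only on `k`, `d` and `m`, never on
`sigma` — the point of the representation.

A note on the enumeration ranges: a formulation that allows wildcards
outside the mismatch region only when `d <= m` under-covers the
intersection. For `k >= 6`, `m = 3`, `d = 4`, a k-mer agreeing with one
parent on two mismatch positions, with the other on two, and differing from
both at one match-region position lies in both neighborhoods but
instantiates no pattern whose wildcards are confined to the mismatch region.
The unified ranges above close this gap and reduce to the simpler rule when
`d <= m`.

**3. Pruning and expansion** (`prune_stems()`, `expand_and_verify()`). A
stem survives when at least `q` records contain a window at *masked*
distance at most `m` (wildcards match anything for free). Two output levels
are reported because they answer different questions:

* **surviving stems** — wildcard patterns in the style of reported
  consensus motifs such as `TGTGAnnnnnnTCACA`;
* **explicit motifs** — the formal solution set: each surviving stem is
  instantiated over the alphabet and every candidate k-mer is individually
  verified against the quorum. Wildcard stems are weak matchers (a stem
  with `w` wildcards only needs `m` matches among `k - w` positions), so
  the explicit, verified level is the one guaranteed to equal the
  brute-force answer; the stem level is faithful to consensus-style
  reporting.

Pruning never discards a stem that covers a true motif (the stem's masked
distance to any window is bounded by the motif's distance), so expansion
after pruning loses nothing; the test suite checks the end-to-end result
against `bruteforce_motif_search()` — an independent exhaustive oracle —
on a hundred seeded instances.

## Numerical and implementation choices

* **Pruning as a masked scan.** The motif property for wildcard-bearing
  patterns is *defined* by the masked-distance scan. The implementation
  accelerates it with counting-sort rounds applied per wildcard-layout
  group (rounds delete `m` of the non-wildcard positions), or a bit-packed
  direct scan where that is cheaper; both are exact and the tests assert
  identity with the naive scan.
* **Quorum abort.** During scans, a pattern is abandoned once the records
  not yet visited cannot lift its match count to `q`. Patterns that reach
  the quorum always run to completion, so reported masks and counts are
  exact for everything the search keeps.
* **Verification against selected windows.** Inside `find_motifs()`,
  explicit candidates are verified against the selected occurrences only.
  This is exact, not an approximation: any window witnessing a record of a
  quorum-passing motif is within `2m` of every matched record (through the
  motif), hence is itself selected. The standalone `expand_and_verify()`
  verifies against all windows, which is the same set.
* **Expansion strategy.** When `sigma^k` fits a bitmap (small alphabets),
  every instantiation is enumerated and deduplicated, with the
  `expansion_cap` guarding the materialized total. For large alphabets the
  wildcards are assigned depth-first with quorum pruning, so only verified
  motifs are ever materialized and no pre-expansion bound is needed.
* **Stem reporting limit.** For small-alphabet instances with large `m`
  relative to `k` (e.g. `k = 11`, `m = 3`, DNA), the Definition-B survivor
  set is enormous — millions of wildcard patterns match trivially because a
  3-wildcard stem needs only 3 matches among 8 positions against 590
  windows per record. The survivor *count* is always reported in the stage
  statistics, but the decoded stem tibble is materialized only up to
  `stem_report_limit` (default 2e5). Explicit motifs are unaffected.
* **Determinism.** Round order is lexicographic in the deleted position
  subsets, stems and motifs are emitted in code order, ties in site
  location break to the leftmost window. Identical inputs give identical
  outputs, and record order only permutes site indices.
* **Degenerate parameters.** `2m >= k` makes the selection vacuous; the
  search warns and proceeds (the result is still exact). `d >= k` in
  selection likewise selects everything with a warning. Records shorter
  than `k` contribute no windows; windows touching symbols outside the
  alphabet are skipped and counted in a warning, since real promoter sets
  contain `N` bases and the method is defined over the declared alphabet
  only.

## Expected-size estimators

`pairwise_match_probability(k, d, sigma)` is the probability that two iid
uniform k-mers disagree in at most `d` positions. From it,
`expected_background_candidates(k, m, n, N, sigma)` estimates how many
k-mers of the whole `sigma^k` space lie within `2m` of at least one window
of every record by chance:

```{r estimators}
pairwise_match_probability(13, 8, 20)
expected_background_candidates(13, 4, 600, 20, 20)
expected_selected_size(1, 13, 4, 600, 20, 20)
```

For a protein-sized instance (`k = 13`, `m = 4`, `n = 600`, `N = 20`,
`sigma = 20`) about 8 chance candidates are expected, and with one
implanted instance the selected set has expected size about 12 — versus
12,000 input k-mers. The window-count convention in the background term is
`t = n` by default (the convention under which the quantities above take
these values); the exact `n - k + 1` is available via the `windows`
argument. Both estimators are evaluated in log space to survive
`sigma^k` overflow.

## The planted-instance simulator

`plant_instance(N, n, sigma, k, m, mode, seed)` reproduces the standard
benchmark protocol: `N` iid uniform strings of length `n`, each with one
implanted copy of a uniformly drawn consensus, mutated at random positions
and overwritten at a uniform offset. The defaults of interest are the
challenge instances `N = 20`, `n = 600`. Two mutation modes exist because
"up to m substitutions" is ambiguous: `"exact"` (the default) always
applies exactly `m` forced substitutions — the convention of the hard
benchmark instances, and the harder search problem — while `"uniform"`
draws the substitution count uniformly from `0..m`. Substituted positions
always receive a different symbol, so the instance distance equals the
substitution count. R's default Mersenne–Twister generator drives all
draws; the seed is recorded in the truth table so instances are citable.

What the simulator does *not* emulate: compositional bias (GC content,
Markov background), multiple motif copies per sequence, gapped or
variable-length motifs, and coincidental extra matches are not rejected.
Passing the planted-recovery tests therefore demonstrates exactness of the
search on iid backgrounds, not robustness to the statistical structure of
real promoters or proteomes.

```{r planted}
pi <- plant_instance(N = 8, n = 100, sigma = 4, k = 7, m = 1, seed = 21)
res <- find_motifs(pi$sequences, k = 7, m = 1)
res
pi$consensus %in% res$motifs
```

Recovery at `q = N` is a hard guarantee, not a statistical one: the
consensus is within `m` of every record by construction, selection keeps
all its instances, the self-pair stems of any instance cover its
neighborhood, and verification is exhaustive over the covered set.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `k` | motif length | — | `k <= 48` |
| `m` | max mismatches | — | `0 <= m < k`; `2m >= k` warns |
| `quorum` | records a motif must match | `N` | CLI accepts a fraction, `ceil(q N)` |
| `pair_policy` | which selected pairs form stems | `"all"` | `"cross-record"` uses only pairs from different records; self-pairs always kept (needed for `N = 1`) |
| `expand` | explicit-motif level | `"auto"` | `"auto"` skips with a warning above the cap |
| `expansion_cap` | materialized-instantiation bound | `2^26` | enumerating path only |
| `minimize` | drop subsumed stems from the report | `FALSE` | never changes explicit motifs |
| `stem_report_limit` | max decoded survivor stems | `2e5` | count always in `glance()` |

On problem sizes: the module tests run on instances up to `N = 6`,
`n = 40`; the oracle-equivalence suites use 100–300 randomized cases; the
planted-recovery suite runs the (9,2,4), (11,3,4), (11,3,20) and (13,4,20)
benchmark instances at `N = 20`, `n = 600` with ten seeds each. The
(11,3,4) instance is the most expensive (roughly half a minute: the
selection condition `d <= 6` barely discards anything over a 4-letter
alphabet, so candidate stems number in the tens of millions); the
large-alphabet instances run in under a second, which is the regime the
method is designed for.

## Known limitations

* Reverse-strand matching is not performed; supply both strands if needed.
* No statistical significance is attached to reported motifs; the search
  is exhaustive, so significance is a property of the instance, not the
  algorithm (existing tools address it separately).
* Wildcard stems carry no position-specific symbol sets; bracket
  expressions appear only in the consensus report
  (`build_consensus()`), e.g. `A[CT]G`.
* The `n` window-count convention in the estimators slightly overstates
  window counts for long motifs; it is exposed as a parameter.
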