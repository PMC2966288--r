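# stemotif

Exact, alphabet-independent discovery of planted (k, m)-motifs in DNA and
protein sequences.

## The problem

Given `N` sequences over an alphabet Σ, find every k-mer `x ∈ Σ^k` whose
Hamming distance to each of at least `q` sequences (the best distance over
all length-k windows of that sequence) is at most `m`. This is the classic
formulation of transcription-factor binding-site discovery (e.g. CRP/FNR/LexA
promoter sets) and of subtle protein-motif finding, where the 20-letter
alphabet makes neighborhood-enumeration algorithms pay a factor of
`V(k, m) = Σᵢ C(k,i)(|Σ|−1)ⁱ`.

`stemotif` implements an exhaustive search whose combinatorial core does not
depend on `|Σ|`:

1. **Selection** — `C(k, 2m)` rounds of counting sort over position-deleted
   k-mers keep exactly the windows within distance `2m` of at least `q`
   records (a necessary condition for being a motif instance, since two
   instances of one motif disagree in at most `2m` positions). The expected
   selected size is `E[I] = t + nN(1 − (1 − p)ᵗ) + E[I_B]` with `p` the
   pairwise ≤ 2m-mismatch probability — about 12 of 12,000 input k-mers for
   a protein-sized instance.
2. **Stem generation** — for each pair of selected k-mers, the set of k-mers
   within `m` of both is represented exactly by wildcard patterns ("stems");
   the number of stems depends only on `k`, `m` and the pair distance.
3. **Pruning & verification** — stems failing the quorum under masked
   distance are pruned; survivors are optionally expanded into explicit
   motif k-mers, each verified individually.

Brute-force oracles (`enumerate_neighborhood()`,
`intersect_neighborhoods_bruteforce()`, `bruteforce_motif_search()`) define
ground truth for every contract, and a planted-instance simulator
(`plant_instance()`) reproduces the standard benchmark protocol with full
truth records.

## Worked example

```r
library(stemotif)

# a (9,2) planted challenge: 20 sequences of length 600, one implanted
# copy of a hidden 9-mer with exactly 2 substitutions in each
pi <- plant_instance(N = 20, n = 600, sigma = 4, k = 9, m = 2, seed = 1)
pi$consensus
#> [1] "ATGACAGGC"

res <- find_motifs(pi$sequences, k = 9, m = 2)
res
#> Motif search result (k = 9, m = 2, quorum = 20)
#>   windows: 11840   selected: 11840   distinct: 11583
#>   candidate stems: 1109339   survivors: 406627
#>   explicit motifs: 4
#>     CCGTGCAGA TATGTGTGA ATGACAGGC TAAAAGATC

pi$consensus %in% res$motifs
#> [1] TRUE

glance(res)   # stage statistics: windows, selected, candidates, survivors
tidy(res)     # one row per motif: records matched, sites, consensus
head(res$sites)  # per-record best sites (0-based offsets)
```

The search is exact: the four reported motifs are *all* k-mers within 2
mismatches of all 20 sequences. They include the planted consensus
`ATGACAGGC` plus three chance motifs — at (9, 2) over a 4-letter alphabet a
few unrelated 9-mers are expected to satisfy the quorum by chance, which is
exactly what makes this a classic "subtle motif" benchmark instance. On a
protein-alphabet instance the selection stage does the heavy
lifting — for `(k, m) = (13, 4)`, `|Σ| = 20`, only ~60 of 12,000 windows
survive selection and the whole search takes well under a second.

Analytic estimators reproduce the expected set sizes:

```r
pairwise_match_probability(13, 8, 20)        # 2.9e-4
expected_background_candidates(13, 4, 600, 20, 20)  # ~8 chance candidates
expected_selected_size(1, 13, 4, 600, 20, 20)       # ~12 selected k-mers
```

## Command line

A thin launcher is installed at
`system.file("exec", "pmotif", package = "stemotif")`:

```sh
pmotif simulate --N 20 --n 600 --sigma 4 --k 9 --m 2 --seed 1 --out out/
pmotif search out/seqs.fasta -k 9 -m 2 --quorum 1.0 --out out/run_
pmotif estimate --k 13 --m 4 --n 600 --N 20 --sigma 20
pmotif eval --truth out/truth.bed --pred out/run_sites.bed
pmotif oracle small.fasta -k 5 -m 1          # brute-force reference
```

Outputs are TSV/BED/FASTA with 0-based half-open coordinates. Exit status:
0 success, 2 usage/validation error, 1 runtime/capacity error.

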