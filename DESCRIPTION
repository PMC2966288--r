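Package: stemotif
Title: Alphabet-Independent Exact Motif Discovery with Wildcard Stems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact solver for the planted (k,m)-motif problem over arbitrary
    alphabets. Candidate motif instances are selected with rounds of
    counting sort over position-deleted k-mers, pairwise Hamming-neighborhood
    intersections are represented compactly as wildcard patterns (stems), and
    stems failing the motif property are pruned before optional expansion to
    explicit motif k-mers. Includes a planted-motif benchmark simulator with
    full truth records, brute-force oracles that define ground truth for every
    contract, expected-candidate-set-size estimators, a site-level performance
    coefficient, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    withr,
    readr,
    ggplot2,
    generics,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
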