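Package: privtree
Title: Privacy-Preserving Decision Tree Induction on Encrypted Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Protects flat tabular datasets (ARFF or headered CSV) for
    outsourced decision-tree analysis: nominal attribute names and values are
    replaced by deterministic AES-256 ciphertexts and numeric values by a
    strictly increasing affine transform, so that C4.5-style gain-ratio tree
    induction on the protected file yields trees equivalent to those induced
    on the plaintext. Includes the owner-side lookup table used to decrypt
    induced decision rules, a J48-like inducer with pessimistic pruning and
    percentage-split evaluation, tree-equivalence checking, bootstrapped
    paired comparisons of original-versus-protected tree metrics, and a
    synthetic mixed-type data generator with planted decision structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    foreign,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
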