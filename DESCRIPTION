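Package: mdrsplit
Title: Multifactor Dimensionality Reduction with Cross-Validation and
    Three-Way Split Internal Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects epistatic (gene-gene) interactions in case-control
    genotype data with Multifactor Dimensionality Reduction (MDR). Two
    interchangeable internal-validation engines are provided: stratified
    m-fold cross-validation with cross-validation consistency and the
    parsimony rule, and a three-way split (training/testing/validation)
    with top-x model carry-forward, including its two-way split variant.
    A post-hoc pruning step based on backward-selection logistic
    regression with genotype indicator variables refines the selected
    locus set. A penetrance-based Hardy-Weinberg case-control simulator
    and a power-evaluation harness (conservative and liberal power,
    average selected-model size, permutation testing) support simulation
    studies of the validation strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
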