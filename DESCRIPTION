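Package: analogynet
Title: Recurrent-Network Simulations of Binary-Choice Verbal Analogy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trains a recurrent triple-completion network on item-relation-item
    propositions and tests it on forced binary-choice verbal analogies
    (A:B::C:[D1|D2]) with a weight-tied twin architecture and an echo-based
    choice rule. Includes a generator for counterbalanced training environments
    whose cells yield analogy questions labelled by semantic facilitation index
    (SFI), backpropagation-through-time learning over the settling dynamics,
    frontal (hidden-bias) and temporal (random connection removal) lesion
    operators, and end-to-end simulations of the developmental relational
    shift and of frontotemporal lobar degeneration lesion patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
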