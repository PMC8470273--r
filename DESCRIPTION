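Package: karyevol
Title: Karyotype Evolution Analysis for Land Snails
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative cytogenetics of helicoid land snails:
    chromosome measurement and Levan-style morphology classification
    (metacentric to telocentric by centromeric index), karyotype formula
    parsing and arithmetic, a rearrangement-event calculus that counts
    translocations and fissions from diploid-number differences and
    pericentric inversions from morphology-class differences, Sankoff
    parsimony reconstruction of ancestral diploid numbers on a phylogeny
    with a brute-force oracle, a stochastic simulator of karyotype
    evolution along trees for method validation, curated karyotype and
    tree fixtures for the superfamily Helicoidea, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
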