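Package: transcores
Title: Aggregated Trans-Effect Genotypic Scores for Core Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs genome-wide trans-effect genotypic scores for gene
    expression (or circulating protein levels) from GWAS summary statistics
    and an LD reference panel, tests the scores for disease association in a
    case-control study, quantifies the effective number of contributing
    trans-eQTLs with a Hill number, and selects putative core genes and
    master-regulator regions under the sparse-effector ("omnigenic") model.
    Includes a synthetic-data generator that emulates the assumed statistical
    structure (sparse cis effects, many weak trans effects, liability mediated
    by core-gene expression) so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
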