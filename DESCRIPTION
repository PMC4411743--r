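Package: gxekit
Title: Polygenic Gene-Environment Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and estimates gene-environment interaction (GxE) for
    polygenic traits with two complementary frameworks. The first scores each
    individual with a genomic risk profile score (GRPS) built from independent
    discovery-sample effect sizes and tests GRPS-by-environment interaction in
    nested logistic (or linear) models with likelihood-ratio tests and decile
    risk stratification. The second estimates a GxE variance component by
    restricted maximum likelihood (average-information REML) from SNP-derived
    genetic and interaction relationship matrices, including a bivariate
    cross-environment model whose genetic correlation below one indicates GxE.
    Includes PLINK bed/bim/fam and GCTA binary GRM input/output, a liability
    threshold cohort simulator with known interaction architecture, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
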