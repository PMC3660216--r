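Package: normpower
Title: Power Limits of Quantile and Rank Normalization in Differential
    Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and theory toolkit for studying how quantile and
    rank normalization limit the testing power of gene differential
    expression analysis.  Provides an equicorrelated log-expression
    simulator, quantile and fractional-rank normalization, per-gene
    two-sample tests (pooled t, Wilcoxon rank-sum, permutation energy
    test) with Bonferroni family-wise error control, replicated power,
    median |t| and density experiments, and the mixture of central,
    noncentral and doubly noncentral t distributions that predicts the
    power plateau of normalized data at large effect sizes.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
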