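Package: allergyrules
Title: Rule-Based Modelling of Gene-Environment Interplay in Childhood Allergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Combines Monte Carlo feature selection with rough-set rule
    induction to identify and validate combinations of SNP genotypes,
    environmental exposures and lifestyle factors associated with allergic
    phenotypes in paired case-control cohorts. Provides a categorical
    decision-table data model, a synthetic two-cohort generator with planted
    main and interaction effects on the odds scale, derivation of eleven
    allergy phenotypes with restricted reference groups, Johnson-heuristic
    reduct computation and IF-THEN rule generation with cross-validated
    model coverage and accuracy, hypergeometric rule significance with
    Bonferroni control, odds ratios with Woolf and Wald confidence
    intervals, cross-cohort direction validation, dose-response analysis,
    and rule co-occurrence networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    igraph,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
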