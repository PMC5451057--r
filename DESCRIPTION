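Package: rarepower
Title: Power and Type-I-Error Simulation for Single- and Multi-Marker
    Rare-Variant Association Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-and-analysis toolkit for comparing single-marker
    Wald t-tests (with minP gene-level decisions under Bonferroni or
    Benjamini-Hochberg correction) against multi-marker tests (an unweighted
    burden test, SKAT, and SKAT-O) for rare-variant association with
    quantitative traits.  Provides a coalescent haplotype-pool engine
    (msprime backend) emulating European-ancestry linkage disequilibrium,
    phenotype generators over a 36-scenario grid of causal fractions, effect
    sizes and effect-direction splits, an exact chi-square-mixture tail
    kernel (characteristic-function inversion with Liu and saddlepoint
    alternatives), Monte-Carlo power and type-I-error estimation at gene and
    variant level, and a censored-regression (Tobit) adjustment stage for
    medication-masked blood-pressure phenotypes with VCF input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    ggplot2,
    withr,
    knitr
LinkingTo: Rcpp, RcppArmadillo
SystemRequirements: Python (>= 3.8) with the msprime package, for
    coalescent haplotype-pool simulation.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
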