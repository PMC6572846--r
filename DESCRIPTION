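Package: ydemos
Title: Y-Chromosome Clade Demography: Admixture Monte Carlo, Coalescent
    Simulation and Skyline Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for inferring male population history from Y-chromosome
    clade frequencies and genealogies. Implements a Monte Carlo estimator of
    ancestral clade frequencies under a two-way admixture model with a
    similarity-index selection rule, a Kingman coalescent simulator with
    piecewise-constant demography and fixed-budget infinite-sites mutation
    dropping, distance-based tree building (neighbor joining and UPGMA) with
    bootstrap support and clade cutting, and a suite of skyline estimators
    (classical, AICc-grouped generalized, and Bayesian with MCMC) for
    reconstructing historical effective population size, together with a
    clade-structured synthetic SNP data generator and haploid VCF input and
    output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
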