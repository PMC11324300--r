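Package: sarcomice
Title: Clinically Anchored Sarcopenia Staging for Mouse Phenotype Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a reusable pipeline for staging sarcopenia in aged
    mice from grip strength, hindlimb muscle mass, and treadmill running
    time. Sex-specific deficit cutoffs are derived as two standard
    deviations below the mean of a young reference cohort; animals are
    staged as non-sarcopenic, probable-sarcopenic, or sarcopenic by
    deficit count, and prevalence is tabulated by age bracket. Includes
    the accompanying statistical decision tree (Shapiro-Wilk gated
    one-way ANOVA with Fisher LSD or Tukey HSD post hoc tests,
    Kruskal-Wallis with Dunn follow-up, Monte Carlo Dunnett many-to-one
    comparisons, Spearman correlations), a competitive gene-set screen
    for protein-trait correlations shared across age cohorts, and a
    Gaussian-copula synthetic cohort and proteomics generator so the
    whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
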