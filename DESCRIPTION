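Package: bnbmla
Title: Bayesian Network Based Bayesian Multilevel Analysis of Relevance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilevel Bayesian relevance analysis for discrete
    genotype-phenotype association studies.  Posterior probabilities of
    structural features of Bayesian networks (direct, transitive,
    confounded and pure-interaction dependence, Markov blanket
    membership and Markov blanket sets, k-subset partial relevance, and
    joint relevance for multiple target phenotypes) are estimated by
    Metropolis-coupled Markov chain Monte Carlo over directed acyclic
    graph structures with a closed-form Dirichlet-multinomial marginal
    likelihood.  Includes exact posteriors by exhaustive enumeration on
    small domains, case-control quality-control filters and frequentist
    association baselines (Hardy-Weinberg tests, allele and genotype
    chi-square tests, odds ratios, Bonferroni correction, logistic
    interaction models), and a synthetic genotype-phenotype simulator
    with known ground-truth relevance structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
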