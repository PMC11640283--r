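Package: mngroups
Title: Genomic Grouping and Risk Stratification of Myeloid Neoplasms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised genomic classification of myelodysplastic and
    myeloproliferative neoplasms from binary mutation and cytogenetic
    profiles. Patients are clustered into genomic groups with a Dirichlet
    process mixture of Bernoulli features (collapsed Gibbs sampling,
    posterior similarity matrix, least-squares consensus partition), groups
    are characterised by pairwise co-occurrence and mutual-exclusivity
    testing, Bayesian-network structure learning, and Bradley-Terry
    inference of mutation acquisition order from clonal fractions, and
    survival risk is stratified with Kaplan-Meier, log-rank and Cox
    proportional-hazards models. Includes a calibrated synthetic cohort
    generator for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
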