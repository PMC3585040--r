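Package: cryptcoal
Title: Coalescent Inference of Stem Cell Division Mode in Intestinal Crypts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation and coalescent-based likelihood
    inference for the mode of stem cell division in intestinal crypts.
    Models the crypt as a two-deme population (stem niche and
    transit-amplifying pool) in which a fraction beta of stem divisions is
    asymmetric, computes the likelihood of single-cell microsatellite
    genotypes by Monte Carlo integration over gene genealogies under a
    two-step stepwise mutation model with Felsenstein pruning, and
    estimates and tests beta across life stages via maximum likelihood,
    marker bootstrap and likelihood-ratio tests. Includes a synthetic
    single-cell study generator, UPGMA trees from model-based distances,
    and age-structured, spatial and continuous-time simulator variants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
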