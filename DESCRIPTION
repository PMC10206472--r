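Package: shelltraits
Title: Phylogenetic Comparative Analysis of Eggshell Surface Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing eggshell surface roughness (Sa),
    wettability (water contact angle) and calcium-carbonate content
    between brood-parasitic birds and non-parasitic species. Implements
    the trait derivations (Sa from profilometry height maps with
    second-order plane correction, contact angle at droplet settling,
    ash-mass CaCO3 percentage), a phylogenetic mixed model with
    REML/ML variance-component estimation and phylogenetic
    heritability (H2), likelihood-ratio tests of fixed effects, and a
    seeded parasite-host versus parasite-random pairwise-difference
    permutation test. A synthetic-data generator (Yule trees, Brownian
    species effects, host-convergence pull, Gaussian height maps)
    provides ground-truth datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
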