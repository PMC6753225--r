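Package: posetcog
Title: Partially Ordered Set Classification of Cognitive Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds identifiable partially ordered set (POSET) classification
    models of cognitive functioning from a neuropsychological battery
    specification, estimates capable and non-capable response distributions by
    Bayesian Markov chain Monte Carlo, classifies subjects to latent cognitive
    profiles by Bayes rule, and compares function-level probabilities of
    high functioning between amyloid-positive and amyloid-negative groups
    within age strata. Includes out-of-bag random forests with permutation
    variable importance for amyloid prediction, and a seeded synthetic-cohort
    generator emulating an amyloid screening population so the full pipeline
    can be exercised without access-restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    randomForest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
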