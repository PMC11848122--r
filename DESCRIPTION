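Package: traitstab
Title: Stability of Species and Functional-Trait Composition in
    Multitrophic Communities
Version: 1.0.0
Authors@R:
    person("Coastal", "Community Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare the temporal stability of species composition
    and community-weighted functional-trait composition in repeatedly
    surveyed communities. Provides trait imputation from measured
    individuals via penalized additive models, community-weighted trait
    matrices, Bray-Curtis dissimilarity, principal coordinates analysis and
    non-metric multidimensional scaling implemented from scratch,
    betadisper-style year-to-centroid and year-to-year stability metrics,
    permutational MANOVA, SIMPER decompositions, ordination vector fitting,
    a mock-community resampling control for dimensional reduction, and a
    synthetic multitrophic survey generator with configurable functional
    redundancy, spatial filtering and compensatory dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
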