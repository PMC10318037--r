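Package: microstab
Title: Microbial Community Structure and the Stability of Soil Ecosystem
    Functions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking soil bacterial community structure
    to the stability of microbial-mediated ecosystem functions under
    stress. Provides repeated-rarefaction alpha diversity, abundance-based
    Raup-Crick (RC-Bray) null-model dissimilarity, principal coordinates
    analysis and a permutational multivariate ANOVA, derived
    biogeochemical process rates (metabolic quotient, net nitrogen
    mineralization and nitrification, total enzyme activity), the
    Orwin-Wardle resistance index, an ecosystem multifunctionality index,
    and tuned random-forest regression with whole-dataset shuffle
    permutation importance for ranking microbial predictors of ecosystem
    function. A synthetic dilution-to-extinction experiment generator with
    planted drivers supports end-to-end validation and parameter-recovery
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
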