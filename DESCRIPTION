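Package: sexcost
Title: Estimating the Net Cost of Sexual Reproduction from Mesocosm
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the net cost of sexual reproduction from
    replicated parent/offspring mesocosm experiments on mixed
    sexual/asexual populations, such as triploid-asexual versus
    diploid-sexual snails scored by flow cytometry.  Implements the
    one-generation asexual-frequency recursion under a net cost of sex,
    beta-binomial maximum-likelihood fitting of candidate cost models,
    small-sample AIC model selection with Akaike weights and bootstrap
    confidence procedures, a binomial logistic test of frequency change,
    the decomposition of the net cost into the cost of males and a
    fecundity-survival ratio, and a synthetic mesocosm-experiment
    generator for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
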