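Package: infagree
Title: Informational Agreement and Cohen's Kappa for Categorical Ratings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inter-rater agreement statistics for dichotomous and multivalue
    ordered-categorical contingency tables. Implements the informational
    agreement index IA -- the mutual information between two raters' category
    assignments normalised by the smaller marginal entropy -- alongside
    Cohen's kappa, using a plug-in (relative frequency) estimate of the joint
    rating distribution. Includes the agreement-channel view (column-stochastic
    transition matrix, sensitivity and specificity, prevalence-insulated
    mutual information), a seeded channel-based rater simulator, zero-cell
    handling via the 0 log 0 = 0 continuity convention with an epsilon-limit
    probe, dichotomisation of ordered scales with exhaustive threshold
    scanning, and utilities to compare classifier agreement patterns via
    Pearson and Spearman correlation of index sequences.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
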