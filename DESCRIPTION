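Package: ihiscore
Title: Visual Scoring, Reliability and Population Analysis of Incomplete
    Hippocampal Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing incomplete hippocampal inversion (IHI, also
    called hippocampal malrotation) from structured visual ratings of
    T1-weighted MRI. Implements the five-criterion ordinal grading scale
    (roundness/verticality of the hippocampal body, collateral sulcus depth
    and orientation, medial positioning, subiculum thickening, fusiform
    sulci), the composite IHI score with accuracy-maximising threshold
    classification against a global reference criterion, Cohen's and
    linearly weighted kappa statistics for rater reliability, prevalence and
    lateralisation analysis with binomial confidence intervals and
    chi-squared tests, and group comparison of sulcal morphometry (pooled
    t-tests, Cohen's d, Bonferroni correction). A calibrated synthetic
    cohort generator reproduces the ordinal marginals, cross-side
    dependence, score separation and sulcal effect sizes of a large
    community sample so that every analysis stage can be exercised without
    access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
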