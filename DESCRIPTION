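Package: kbdsig
Title: Blood-Based Gene Expression Signature Discovery for Kashin-Beck Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and validating blood-based transcriptional
    signatures of Kashin-Beck disease (KBD), an endemic osteochondropathy,
    from paired two-color microarray experiments. Implements two-channel
    spot-level preprocessing (quality filtering, background correction,
    global normalization, per-pair expression ratios), differential-expression
    screening by fold-change plus Bonferroni-adjusted paired t-tests,
    minimum-redundancy maximum-relevance (mRMR) gene ranking inside a
    leave-one-out cross-validation wrapper around a linear support vector
    machine, Bayes (linear) discriminant classification of disease degree,
    and orthogonal validation statistics (2^-ddCt relative quantification,
    Mann-Whitney rank-sum tests, age-association checks). A synthetic-cohort
    generator with planted differential effects makes every stage testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    e1071,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
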