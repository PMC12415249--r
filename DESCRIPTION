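Package: deniscan
Title: Directional Phenotype-Profile Matching for Hominin Crania
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well candidate hominin crania match a directional
    Denisovan phenotype profile against modern-human and Neanderthal reference
    distributions. Implements interpolated empirical-quantile estimation with
    Tukey outlier removal, signed phenotypic distances, binomial (mid-p) and
    Wilcoxon signed-rank profile scores, a constraint-preserving permutation
    null, Denisovan-versus-Neanderthal differentiation scoring, iterative-PCA
    missing-data imputation with reference-group morphospace projection,
    mandibular prediction validation, and a synthetic craniometric study
    generator for end-to-end testing without access to the original specimen
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
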