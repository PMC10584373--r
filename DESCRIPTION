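Package: morphsig
Title: Morphological Signatures of Drug Resistance from Cell Painting Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers and applies morphological signatures of drug
    resistance from well-level Cell Painting profiles. Implements the
    image-based profiling stages (median aggregation, platemap annotation,
    per-plate z-score normalization, rule-based feature selection),
    covariate-adjusted per-feature linear modelling with Tukey-Kramer
    post-hoc screening and Bonferroni-thresholded exclusion rules,
    directional rank-based signature scoring (singscore) with a
    permutation null and high-confidence calls, and an evaluation suite
    (accuracy, average precision, ROC/AUROC, clone-shuffled baselines,
    cluster-enrichment diagnostics, Kolmogorov-Smirnov misclassification
    diagnostics). Ships a synthetic-profile generator that plants known
    resistance features and technical confounders for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
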