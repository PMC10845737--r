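Package: hscrdss
Title: Robustness Evaluation Toolkit for Algorithm-Assisted Hirschsprung
    Disease Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the robustness of a decision support system
    (DSS) for the histopathological diagnosis of Hirschsprung's disease
    across laboratories and whole-slide scanners. Implements the
    score-combination case-classification rule with expert-referral logic,
    image-set-level false-positive/false-negative discordance detection with
    a causative-factor taxonomy, cohort- and scanner-level performance
    tabulation with chi-square comparison of error profiles, and RGB
    histogram colour-distribution analysis using a normalized
    squared-Euclidean distance. Seeded synthetic generators for
    algorithm/pathologist score cohorts and H&E-like image tiles under
    parameterized stain and scanner effects make every pipeline stage
    testable without access to clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    png,
    tiff,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
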