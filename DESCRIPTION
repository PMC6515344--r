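Package: circlin
Title: Circular-to-Linear Ratio Analysis for circRNA Biomarker Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies circular RNA abundance relative to linear splicing from
    back-splice junction counts (CIRI2-style tables and STAR splice-junction
    tables), computes per-sample circular-to-linear ratios using the most
    abundant linear junction sharing a donor or acceptor site, performs qPCR
    delta-delta-Ct analysis of circular fractions with normality-gated
    two-group testing and two-stage Benjamini-Krieger-Yekutieli false
    discovery rate control, combines significant features into a per-sample
    circular-to-linear score, and evaluates the score as a disease biomarker
    via ROC curves and correlations with muscle-strength and splicing
    covariates. Includes a synthetic-cohort generator with planted effects
    and ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
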