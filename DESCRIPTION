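Package: metaahp
Title: Meta-Analytic Hierarchy Process Risk Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building composite geographic risk indices from
    published epidemiological evidence. Per-study odds or risk ratios are
    pooled with an inverse-variance random-effects meta-analysis (with
    Cochran's Q, I-squared, DerSimonian-Laird tau-squared, and Egger/Begg
    publication-bias diagnostics), pooled effect sizes are converted to
    priority weights via the Analytic Hierarchy Process (principal
    eigenvector of a positive reciprocal pairwise comparison matrix, with
    Saaty consistency checking), and the weights are combined with regional
    exposure data into composite risk indices in either binary-exposure or
    z-score mode, together with outcome correlation and sensitivity
    analyses. A seeded synthetic-data generator provides study and region
    tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
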