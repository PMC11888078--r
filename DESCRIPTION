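Package: cuatrial
Title: Trial-Based Cost-Utility Analysis with Multiple Imputation and
    Bootstrap Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for trial-based cost-utility analyses of two-arm
    randomized trials. Computes quality-adjusted life years by the
    area-under-the-curve rule, builds bottom-up direct medical cost and
    human-capital productivity cost ledgers, performs chained-equation
    multiple imputation with predictive mean matching and Rubin's-rules
    pooling, estimates baseline-adjusted incremental costs and QALYs by
    seemingly unrelated regression, and propagates uncertainty by
    nonparametric stratified bootstrap into incremental cost-utility
    ratios, cost-effectiveness planes, and cost-effectiveness
    acceptability curves. Includes control-arm trajectory extrapolation
    for designs with truncated control follow-up and a calibrated
    synthetic trial generator so the full pipeline can be exercised
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
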