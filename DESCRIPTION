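Package: anchorcut
Title: Anchor-Based Standard Setting with Normal-Theory Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates examination cut-scores from a panel of judges who each
    report two whole-exam anchor scores: the highest score that still indicates
    clear incompetence (L, the clear-fail anchor) and the lowest score that
    indicates clear competence (H, the clear-pass anchor). The cut-score is
    placed where the two anchor means are an equal number of standard errors
    away, by solving Z*SE_L + Z*SE_H = H - L; the method also reports the
    normal-theory confidence attached to that placement, a one-tailed p-value,
    and a 95% confidence interval built from the two independent anchor
    variances. Includes panel summarisation with trimming and bootstrap
    standard errors, normality diagnostics, classic Angoff and
    direct-suggestion baseline cut-scores, a seeded judge-panel simulator with
    an analytic population oracle, CSV/JSON/YAML input-output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
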