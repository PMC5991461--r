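# anchorcut

Group standard setting for criterion-referenced examinations, for
psychometricians and assessment teams who run judge panels. Instead of
asking judges to imagine a "minimally competent" examinee item by item
(classic Angoff), each judge answers two whole-exam questions: the highest
score that still indicates **clear incompetence** (L, the clear-fail
anchor) and the lowest score indicating **clear competence** (H, the
clear-pass anchor). The cut-score is placed where both anchor means are
the same number of standard errors away:

```
Z·SE_L + Z·SE_H = H̄ − L̄     ⇒     Z = (H̄ − L̄) / (SE_L + SE_H)

CS = L̄ + Z·SE_L = H̄ − Z·SE_H
```

with a normal-theory confidence level `2·Φ(Z) − 1` (68% / 95% / 99.7% at
Z = 1/2/3), a one-tailed p-value `1 − Φ(Z)`, and — while |Z| < 1.96 — a
95% CI running from `H̄ − 1.96·SE_H` up to `L̄ + 1.96·SE_L`. Because the two
anchor variances differ, the cut-score is pulled toward the anchor the
judges agreed about more tightly, which moderates extreme judges.

The package also provides panel summarisation with trimming and bootstrap
SEs, normality diagnostics, classic-Angoff and direct-suggestion baseline
cut-scores, and a seeded judge-panel simulator with an analytic population
oracle for property studies. See `vignettes/anchored-cutscore.Rmd` for the
model, assumptions and design choices.

## Worked example

A pilot panel of 17 judges with anchor means 62.65 (L) and 65.35 (H) and
standard errors 5.609 and 3.193 — entered directly from the panel's
descriptive table:

```r
library(anchorcut)
s <- panel_summary(n = 17, mean_L = 62.65, se_L = 5.609, sd_L = 23.12,
                   mean_H = 65.35, se_H = 3.193, sd_H = 13.16,
                   label = "pilot exam")
compute_cut_score(s)
```

```
Anchored cut-score report
=========================
exam: pilot exam
judges: n = 17 (SE method: analytic)
clear-fail anchor L: mean 62.65, SE 5.61
clear-pass anchor H: mean 65.35, SE 3.19
Z = 0.307
cut-score = 64.37 (from L: 64.37; from H: 64.37)
confidence = 24.1%
one-tailed p = 0.38
95% CI = (59.09, 73.64); CI midpoint = 66.37
L/H midpoint = 64.00
```

Reading it: the panel's anchors are 2.70 points apart against a combined
SE of 8.802, so Z = 0.307 and the cut-score lands at 64.37 from either
anchor — slightly above the plain L/H midpoint (64.00) because the judges
agreed more tightly about the clear-pass anchor. The small Z means modest
confidence (24.1%) that this point cleanly separates the two anchor
distributions; the 95% CI (59.09–73.64) is applicable since |Z| < 1.96,
and its midpoint (66.37) differs from the cut-score because the interval
combines two different variances. An examinee scoring 65 passes
(`classify_examinee(65, res)`), annotated as falling inside the CI.

Raw per-judge data go in the same way via CSV:

```r
panel <- read_panel_csv("panel.csv")     # judge_id,L,H[,suggested]
res   <- compute_cut_score(summarize_panel(panel))
write_report(res, "report.json", format = "json")
```

A command-line interface with `cutscore`, `baseline-angoff`,
`baseline-suggested`, `simulate` and `study-confidence` subcommands ships
at `system.file("cli", "anchorcut.R", package = "anchorcut")`.

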