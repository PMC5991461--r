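---
title: "Anchored cut-scores: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored cut-scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorcut)
```

## The standard-setting problem

A criterion-referenced examination needs a cut-score: the score at and
above which an examinee passes. Classic Angoff panels derive it from
item-by-item judgements about a hypothetical "minimally competent"
examinee — a notoriously vague referent. The method implemented here asks
each judge two whole-exam questions instead, both about what is *clear*
rather than what is borderline:

* **L** — the highest score that still indicates the examinee is clearly
  incompetent (the clear-fail anchor);
* **H** — the lowest score that indicates the examinee is clearly
  competent (the clear-pass anchor).

Both are percents on the exam's score scale. The zone between the panel
means $\bar L$ and $\bar H$ is where judges, collectively, are no longer
sure either way; the cut-score is placed inside it.

## The model

Treat the judges' L's and H's as samples from two independent
approximately normal distributions, with standard errors of the means
$SE_L = SD_L/\sqrt{n}$ and $SE_H = SD_H/\sqrt{n}$. The cut-score $CS$ is
defined as the point lying the *same* number $Z$ of standard errors above
$\bar L$ as below $\bar H$:

$$Z \, SE_L + Z \, SE_H = \bar H - \bar L
  \quad\Longrightarrow\quad
  Z = \frac{\bar H - \bar L}{SE_L + SE_H},$$

$$CS = \bar L + Z\,SE_L = \bar H - Z\,SE_H.$$

The two placements are algebraically identical; `compute_cut_score()`
computes both and the test-suite asserts their agreement to $10^{-9}$ on
randomized summaries. Because the two variances are generally unequal,
$CS$ is *not* the midpoint of $\bar L$ and $\bar H$: it is pulled toward
the anchor the judges agreed about more tightly, which is what moderates
the influence of a single extreme judge.

Three further quantities are attached:

* **confidence** $= \max(0,\, 2\Phi(Z) - 1)$ — the normal mass separating
  the two anchor distributions at the interface; it reproduces the
  familiar 68% / 95% / 99.7% at $Z = 1, 2, 3$;
* **one-tailed p** $= 1 - \Phi(Z)$;
* **95% CI** $= (\bar H - 1.96\,SE_H,\ \bar L + 1.96\,SE_L)$ — the lower
  bound comes from the clear-pass anchor (any lower score falls below
  every plausible H) and the upper bound from the clear-fail anchor. The
  construction is only coherent while the bands overlap, i.e. while
  $|Z| < 1.96$; beyond that the interval self-inverts and is reported as
  *not applicable* rather than replaced by a different construction. The
  CI midpoint generally differs from $CS$ because the interval mixes two
  different variances; reports print both midpoints side by side.

```{r worked}
s <- panel_summary(n = 17, mean_L = 62.65, se_L = 5.609,
                   mean_H = 65.35, se_H = 3.193, label = "pilot exam")
compute_cut_score(s)
```

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `scale_max` | percent | 100 | exams reported on a 0–100 percent scale |
| CI applicability threshold | Z units | 1.96 | the CI itself is built from 1.96, so the same constant gates it (not the looser "2") |
| trimming `k_per_side` | judges | 0 | trimming is a remedy, never automatic |
| bootstrap `replicates` | resamples | 2000 | SE of a mean stabilises well below this; seed is mandatory for audit |
| pass rule | — | at-or-above | a score exactly at `CS` passes |

## Conventions and numerical choices

* **Sample SD uses the $n-1$ denominator** — the standard inferential
  convention for SEs of means. When a summary is built from a published
  descriptive table, the printed SEs are taken as authoritative rather
  than re-derived from rounded SDs (rounding a SD to 2 dp and dividing by
  $\sqrt n$ loses the third decimal of the SE).
* **Full precision internally, report rounding only at the surface**: Z to
  3 dp, scores and CI bounds to 2 dp, percentages to 1 dp, ties rounded
  away from zero as in hand-rounded tables.
* **Judges with $L > H$** are internally inconsistent but retained by
  default (with a warning): the two questions are independent and silent
  deletion would bias the panel. `drop_inconsistent = TRUE` excludes them.
* **Degenerate panels** (both SEs zero): equal means return that mean with
  confidence 0 and a flag; distinct means have no finite Z and error out.
* **Inverted anchors** ($\bar H < \bar L$): Z is negative, confidence is
  clipped to 0, and the result carries `anchors_inverted = TRUE` — still
  reportable for audit, never silently repaired.
* **Trimming ties**: judges are ordered by the chosen anchor with a stable
  sort, so ties at a trim boundary resolve by input order.
* **Confidence formula**: defined once as $2\Phi(Z)-1$, validated against
  the 68/95/99.7 calibration. (A verbal account of the worked example in
  circulation quotes "25%" where the formula gives 24.1%, alongside tail
  areas that do not sum consistently; the calibration at $Z = 1,2,3$ is
  taken as the definition.)

## What the simulator emulates

`simulate_panel()` draws each judge's L and H independently from
(optionally skew-)normal populations truncated to the score scale, with
optional contamination (a fraction of judges shifted by a fixed offset) to
emulate extreme panellists.

* **Truncation by redraw**, not clipping (cap: 1000 rounds of redraws),
  so the shape inside the bounds is preserved; bounds that exclude nearly
  all mass error out.
* **Skew** uses the skew-normal with location and scale re-solved so the
  requested mean and SD are preserved — skewed and unskewed configurations
  stay comparable. This is a testing device for the normality assumption,
  not part of the method.
* **Seeding**: one master seed; replicate panels inside
  `confidence_curve()` run on substreams derived deterministically from
  (seed, replicate, panel size), so studies are reproducible end to end.

`population_result()` is the analytic oracle: the engine applied to the
population parameters with $SE = \sigma/\sqrt n$. It refuses skewed,
contaminated, or heavily truncated configurations (bounds removing more
than 10% of either anchor's mass); below that it treats the populations as
untruncated normals and is mildly approximate. Parameter-recovery tests
therefore use population SDs (15 and 10 percent) that keep over 99% of the
mass inside the 0–100 scale; the confidence-versus-panel-size study uses
the wider pilot-like SDs (23.12, 13.16), where simulated means are
compared only for monotonicity.

The simulator does **not** emulate: correlation between a judge's L and H
(drawn independently; real judges are likely positively correlated, which
would shrink the variance of $\bar H - \bar L$ but leaves each anchor's SE
untouched), judge-by-exam interactions, discreteness of real mark scales,
or examinee score distributions. Passing simulation tests therefore
certify the estimator's behaviour under the model's own assumptions, not
the behaviour of any real panel.

## Problem sizes in the test-suite

Property tests run on hundreds of randomized summaries; Monte-Carlo checks
use 200–500 replicate panels at panel sizes 17–500 and a bootstrap
convergence check at 20,000 resamples — sizes at which the Monte-Carlo
error of a mean confidence is well under the asserted margins while the
whole suite stays in the tens of seconds.

## Known limitations

* Normal-theory confidence is only as good as the normality of the
  anchors; with 15–20 judges, `normality_diagnostics()` has limited power,
  which is why its flag is advisory rather than blocking.
* The method takes the panel as given: it quantifies judge disagreement
  but cannot detect shared bias (all judges too lenient shifts everything).
* With $|Z| \ge 1.96$ no CI is reported; the package deliberately does not
  invent an alternative interval for well-separated anchors.
* The direct-suggestion and classic-Angoff baselines are comparators only;
  no reconciliation between methods is attempted.
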