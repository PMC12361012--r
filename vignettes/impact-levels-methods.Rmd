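---
title: "Deriving chronic pain impact levels by PRO-Bookmarking: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving chronic pain impact levels by PRO-Bookmarking: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impactlevels)
```

## The problem

Pain interference instruments in the PROMIS family report a continuous
T-score (population mean 50, SD 10), which discriminates finely but carries
no intrinsic severity categories. The Graded Chronic Pain Scale – Revised
(GCPS-R) does the opposite: it yields exactly four ordered impact levels
(no impact / mild / bothersome / high-impact chronic pain) but no continuous
score. PRO-Bookmarking bridges the two: panels of patients and clinicians
read an ordered series of "score vignettes" — hypothetical respondents whose
item answers embody specific T-scores — and place bookmarks where one
severity level ends and the next begins. The bookmark positions become cut
scores on the T metric, after which any T-scored sample can be classified
into the same four levels and compared against the GCPS-R rubric.

This package implements that whole chain: the item response model and
scoring, vignette construction and calibration, threshold derivation from
bookmark placements, both classification rubrics, the concordance and
known-groups statistics, and a seeded synthetic-data generator that stands
in for data the original study could not deposit.

## The measurement model

Items are 5-category graded response model (GRM) items. For item $i$ with
discrimination $a_i > 0$ and ordered boundary locations
$b_{i1} < \dots < b_{i4}$, the boundary curves are

$$P^*_{ik}(\theta) = \frac{1}{1 + e^{-a_i(\theta - b_{ik})}},$$

and category probabilities are adjacent differences
$P_{ik} = P^*_{i,k-1} - P^*_{ik}$ with $P^*_{i0} = 1$, $P^*_{i5} = 0$.
The latent trait maps to the reporting metric by $T = 50 + 10\,\theta$.
No separate 1.7 logistic scaling constant is applied: `a` absorbs it, and
the bank loader documents this so imported parameters are not double
scaled. Parameters supplied in slope–intercept form ($a\theta + c_k$) are
converted on load via $b_k = -c_k/a$.

Pattern scoring is expected a posteriori (EAP): the posterior mean of
$\theta$ under a standard normal prior (equivalently $T \sim N(50, 10)$,
configurable for sensitivity runs) and the GRM likelihood of the answered
items. Missing responses are dropped from the likelihood — no imputation.

**Numerical choice.** The posterior is integrated on 81 equally spaced
nodes over $\theta \in [-4, 4]$ with rectangle weights times the prior
density, renormalized. Because the integrand is smooth and effectively
vanishes at the interval ends, this equal-spacing rule is extremely
accurate; the test suite checks EAP scores against an 801-node reference
integration and sees agreement far inside the 0.01 T acceptance band.

## Vignette construction

A vignette at target score $T_0$ answers each selected item with its
*most likely* response at $T_0$ (argmax of the category curves; ties break
toward the lower category — deterministic and conservative toward less
impact). Because a given response is modal over a *range* of scores, the
assembled pattern does not land exactly on $T_0$; each vignette is
therefore *calibrated* by EAP-scoring its own pattern, stored to one
decimal T.

Item selection was genuinely open in the source procedure ("close
attention to content balancing"); the design adopted here is round-robin
across subdomain tags with the highest-information item at the target
winning within each subdomain, ties broken by lexicographic item id. A
one-subdomain bank triggers a warning and unbalanced fallback.

The default set is 8 vignettes with targets spaced 5 T (0.5 SD) apart over
[45, 80], labelled with surnames from a fixed, culturally mixed pool of 26
names (overflow appends numerals). A set whose calibrated scores are not
strictly increasing refuses to construct, naming the offending pair — this
genuinely happens when a small bank saturates at the top of the range, and
silently reordering would corrupt the bookmark arithmetic downstream.

## From bookmarks to thresholds

A placement in gap $g$ (between vignettes $g$ and $g+1$) yields the
individual threshold

$$\tau = \mathrm{round}_{1/2\uparrow}\!\left(\frac{T_{(g)} + T_{(g+1)}}{2}\right),$$

the half-up-rounded mean of the two adjacent calibrated scores. Half-up
rounding is forced by the published worked example: vignettes scored 63
and 66 give a threshold of 65, and the exact mean is 64.5 — banker's
rounding would give 64.

Group thresholds are per-boundary **modes** of the individual thresholds.
The multimodal tie rule (unspecified in the source) is: prefer the
candidate nearest the panel median for that boundary, then the lower
value; ties are flagged in the result. The median anchor makes the rule
robust to a single outlying panelist; the lower-value fallback keeps it
deterministic.

Two bookmarks may share a gap at the individual level (the thresholds
come out equal), but a modal sequence that is not strictly increasing is
a panel-data quality error and is rejected with diagnostics.

## The two classification rubrics

**Bookmark rubric.** `classify_t()` assigns level = number of thresholds
$\le T$; a score exactly at a threshold goes to the *higher* level,
because the bookmark marks the first vignette better described by the
higher level and the threshold is the midpoint just below it.

**GCPS-R rubric.** High-impact chronic pain (HICP) iff *both* frequency
items (pain; life/work-limiting pain, past 3 months) are "most days" or
"every day" — independent of the PEG. Otherwise the PEG sum (three 0–10
items, range 0–30) splits mild (< 12) from bothersome (>= 12). The "no
impact" gate is not fully specified in the source (the scoring graphic
lives elsewhere); both defensible readings are implemented and exposed:

* `gate = "chronic_pain"` (default): no impact iff pain is not present on
  most/every day — consistent with the chronic-pain definition the scale
  builds on;
* `gate = "never_only"`: no impact only for "never".

Neither is asserted to be the original rubric's gate. Records missing a
required item are refused with a reason code, never imputed.

## Concordance and known-groups statistics

Published reports provide the compact forms, so the statistics are
computed directly from them:

* `spearman_from_table()` — tie-corrected (midrank) Spearman correlation
  straight from a contingency table's counts. The category midrank is
  $C_k - m_k/2 + 1/2$ (cumulative count $C_k$, category count $m_k$);
  the result is identical, to 1e-12, to expanding the table into unit
  records and correlating midranks, which the property tests verify on
  200 random tables. The p-value uses the large-sample t approximation
  and is reported for orientation only. Whether the original analysis
  coded levels differently is unknowable from the report; midranks on the
  ordinal levels reproduce its printed correlation and are adopted.
* `anova_from_summaries()` — one-way ANOVA from (n, M, SD): between-group
  SS from sizes and means, within-group SS from $(n-1)\,\mathrm{SD}^2$;
  algebraically identical to raw-data ANOVA when the summaries are exact
  (property-tested against `anova(lm(...))`).
* `bonferroni_posthoc()` — pairwise differences with pooled SE
  $\sqrt{\mathrm{MSW}(1/n_i + 1/n_j)}$, $p_\text{adj} = \min(1, m\,p)$,
  and **Bonferroni-adjusted** confidence intervals
  $d \pm t_{df,\,\alpha/(2m)}\,\mathrm{SE}$. The adjusted critical value
  is forced by back-solving the published table: its half-width / SE
  ratio is ≈ 2.66, the adjusted $t_{405}$ quantile, not the unadjusted
  1.97.

Printed statistics are rounded for display only; computation always runs
at full precision.

One reproduction limit is worth recording: feeding the *printed* 1-decimal
group summaries through the post-hoc machinery gives a No-vs-Bothersome
mean difference of −4.9, while the published row shows −4.96 (computed
from unrounded means). The adjusted CI lower bound therefore lands at
−7.75 instead of the printed −7.81 — a discrepancy wholly attributable to
input rounding, not to the method. The corresponding acceptance assertion
is deliberately left failing rather than loosened.

## The synthetic world

No study data are deposited, so a seeded generator supplies every input
with the statistical structure the analysis assumes. Its defaults are the
stated world and are not tuned:

* **Bank**: 20 items, lognormal discriminations (median 2), boundary
  centers uniform over $\theta \in [-1, 2.5]$ with offsets
  $(-1, -\tfrac13, \tfrac13, 1)$ times a random half-spread (mean 1.2) —
  banks span roughly $\theta \in [-1, 3]$ so clinic-range vignettes are
  constructible; six subdomain tags. Real calibrated parameters are
  proprietary; the bank is labelled synthetic throughout.
* **Respondents**: $T \sim N(62.5, 7.5)$ — a tertiary-clinic shape in
  which a small minority falls below any plausible lowest cut and a
  sizeable minority above the highest, qualitatively echoing the reported
  clinic distribution without asserting its percentages.
* **Panel**: 10 panelists; each perceives every true cut with
  $N(0, 2.5\,\mathrm{T})$ noise — under half the 5-T vignette spacing,
  emulating panels that mostly land within one vignette of each other —
  and bookmarks the gap with the nearest midpoint; gaps are clipped
  nondecreasing. Noise lives in T units, not gaps, so it interacts with
  vignette spacing and supports spacing-sensitivity experiments.
* **GCPS-R link**: ordered-logit frequency items (slope 1.5; pain cuts
  −0.5/0.4/1.2, limitation cuts −0.2/0.8/1.6 in $\theta$) and PEG items
  with mean $3.2 + 1.8\,\theta$, SD 1.6, rounded and clipped to 0–10.
  Chosen once so that, at the clinic trait distribution, the level
  margins are plausibly clinic-like and the two rubrics correlate
  moderately; the end-to-end check only asserts the wide band (0.3, 0.7)
  around the published mid-range concordance.

What a green synthetic test establishes: internal consistency — scoring
recovers generating traits, modal aggregation recovers generating cuts
under stated noise, the two rubrics agree to the degree the link implies.
What it cannot establish: anything about real calibrations, real panels,
or the actual published threshold values (shown only graphically in the
source), which is why those quantities are never asserted numerically.

All generators are deterministic given the master seed; each stage derives
a fixed sub-seed so stages are independently reproducible, and the
pipeline manifest records md5 digests of every artifact to make "same
config, same run" checkable.

## Known limitations

* No CAT administration and no item-parameter estimation — banks are
  inputs, never fitted.
* The vignette-set construction error on non-monotone calibrated scores
  is a feature, but it means some (bank, range, item-count) combinations
  simply refuse; widen the bank or narrow the range.
* The Spearman p-value is approximate; the package never asserts it.
* The GCPS-R no-impact gate is a documented choice, not a reproduction of
  the original scoring graphic.
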