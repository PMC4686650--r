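---
title: "Scoring incomplete hippocampal inversion: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring incomplete hippocampal inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihiscore)
```

## The problem

Incomplete hippocampal inversion (IHI, also called hippocampal malrotation)
is an atypical anatomical configuration of the hippocampus — a round or
verticalised, medially positioned hippocampal body accompanied by a deep
collateral sulcus — of presumed developmental origin. It is common in the
general population, strongly left-lateralised, and over-represented in
epilepsy and malformations of cortical development. Characterising it at
cohort scale requires (i) a reproducible visual rating scale, (ii)
reliability statistics for the raters applying it, (iii) prevalence and
lateralisation estimates with uncertainty, and (iv) a way to relate the
resulting phenotype to other morphometric measurements. `ihiscore`
implements all four stages, plus a calibrated synthetic cohort generator so
the pipeline can be exercised and validated without access to restricted
imaging cohorts.

## The rating scale

Five criteria are graded per hippocampus on coronal slices:

* **C1 — roundness and verticality** of the hippocampal body. Roundness
  compares the body's width and height (flat / round / oval); verticality
  bins the width segment's angle from the horizontal (horizontal / oblique /
  vertical). The grade is a table lookup on the pair; a flat *and* vertical
  body is anatomically contradictory and is rejected rather than graded.
* **C2 — collateral sulcus**: whether its fundus reaches the lateral limit
  of the hippocampus, and its orientation. Deeper and more vertical sulci
  grade higher.
* **C3 — medial positioning**: the uncovered subiculum length relative to
  the part covered by the dentate gyrus, modulated by whether the temporal
  horn is emptied or CSF-filled. The two extreme exposure relations grade
  2 and 0 regardless of the temporal horn.
* **C4 — subiculum**: binary; a subiculum bulging upward (thickened)
  grades 2, otherwise 0.
* **C5 — fusiform-gyrus sulci**: whether the collateral or
  occipito-temporal sulcus crosses the level of the subiculum, and if so
  with oblique (1) or vertical (2) orientation.

The **IHI score** is the sum C1+…+C5, ranging 0–10 on a 0.5 grid. A
global criterion **C0** (0 no, 1 partial, 2 total IHI) provides a holistic
reference judgment.

### Geometric adapters are a formalisation, not part of the scale

The scale is applied visually, without tracing segments.
`classify_roundness()`, `classify_verticality()` and `exposure_relation()`
exist so that quantitative landmark measurements *can* drive the same
grading tables, and their tolerances are package choices, not published
calibrations:

* roundness equality tolerance: 10 % of the larger segment — two segments
  within 10 % are visually indistinguishable;
* verticality: horizontal ≤ 10°, vertical ≥ 80°, oblique between — the
  scale's own "tolerance of around 10°";
* exposure-ratio cut points 0.25 / 0.8 / 1.25 / 4, approximately symmetric
  on the log scale around 1, with a ratio of exactly zero (invisible
  uncovered subiculum) always mapping to the lowest bin. Cut points are
  left-closed: a ratio exactly at an edge falls in the upper bin.

All three are configurable arguments.

## Threshold classification

To dichotomise the score, `optimal_threshold()` uses only hippocampi whose
global judgment is unambiguous (C0 = 0 or C0 = 2), evaluates every midpoint
between consecutive distinct observed scores as a candidate threshold, and
returns the candidate maximising the accuracy of the rule
`score > threshold`, breaking ties towards the smallest candidate. Because
scores live on a 0.5 grid, fitted thresholds are off-grid midpoints such as
3.75, which makes `score > 3.75` identical to the "IHI iff score ≥ 4" rule:

```{r threshold}
fit <- optimal_threshold(score = c(2, 3, 3.5, 4, 5),
                         c0    = c(0, 0, 0, 2, 2))
fit
```

Partial cases (C0 = 1) never enter the fit but are classified by the fitted
threshold when the whole population is dichotomised
(`threshold_frequency_table(..., mode = "classify_all")`); the
`"exclude_partial"` mode instead keeps them out of the IHI / no-IHI split
while leaving them in the denominator, which is how per-side frequency
tables are conventionally reported.

## Rater reliability

`cohen_kappa()` and `weighted_kappa()` compute chance-corrected agreement
from a confusion table built over the criterion's *full* category set
(unused grades are retained so chance agreement is computed on the whole
grid). Weighted kappa uses linear disagreement weights
$d_{ij}=|i-j|/(k-1)$ by default: the half-point grades are equally spaced,
so a one-step disagreement should cost a fixed fraction of a maximal one;
quadratic weights are available as an option. With two categories both
statistics coincide. Standard errors use the Fleiss–Cohen–Everitt
large-sample form with a symmetric normal interval; this is a deliberate
simplification — published reliability tables for this scale include at
least one asymmetric interval whose method is not stated, so no attempt is
made to match such values numerically.

`reproducibility_report()` mirrors the two-rater, two-session design (two
intra-rater and two inter-rater comparisons per criterion), applying
weighted kappa to C1–C3 and plain kappa to C0, C4, C5. A criterion on
which both series are constant and identical — C4 in practice, since a
thickened subiculum is rare (~3 % of hippocampi) — has chance agreement 1
and no defined kappa; it is flagged `evaluable = FALSE` rather than
computed.

## Prevalence and lateralisation

Binomial proportions use the Wald interval by default, clipped to [0, 1],
because that is the method that reproduces the published per-side C0
intervals from their frequencies at n = 2008; the Wilson interval is
available (`method = "wilson"`) and preferable near the boundaries.
`proportion_ci()` accepts non-integral counts so intervals can be
reconstructed from rounded published percentages at a known n.

Chi-squared tests are plain Pearson without continuity correction.
The left-vs-right comparison treats a subject's two hippocampi as
independent samples — replicating the conventional analysis — and a
Stuart–Maxwell marginal-homogeneity variant
(`side_comparison(method = "stuart_maxwell")`) is provided for the
methodologically correct paired analysis. Missing covariates (handedness
is incomplete in real cohorts) are excluded listwise per test and counted
in an `excluded` attribute, never silently dropped.

## Sulcal morphometry association

`build_groups()` forms, per side, an IHI group (score above threshold on
that side) and a single non-IHI group (no IHI on *either* side); a subject
with IHI only on the opposite side belongs to neither group for that
side's comparison. `run_association()` then compares every
(sulcus, measure) cell in four directions (left/right IHI × ipsi- and
contralateral hemisphere) with a pooled-variance Student t-test — pooled
rather than Welch to match the conventional analysis; effect sizes are
Cohen's d with the IHI-minus-non-IHI sign convention, so
$d = t\sqrt{1/n_a + 1/n_b}$ holds cell-wise.

Correction is Bonferroni with a **fixed design denominator of 900**
(45 sulci × 5 measures × 4 directions), kept even when cells are missing,
so that corrected p-values remain comparable across analyses. Sulcus
length is carried as a sixth measure in the data model (it appears in
published effect tables) but does not enlarge the default denominator; the
discrepancy is deliberate and surfaced here. Analysis is complete-case per
cell, which is why effective group sizes vary across cells.

## The synthetic generator

The generator's defaults encode the study conditions the analysis code is
meant to face; they are fixed, documented study emulation, not tuning
knobs.

**Grades.** Each subject has one latent severity per hemisphere, bivariate
normal with correlation `side_coupling = 0.9`. Each criterion draws a
latent value loading on the side's severity
(`criterion_loading = 0.5`) plus independent noise, and its normal
quantile is cut at the criterion's marginal grade distribution (a Gaussian
copula). The marginals default to the published per-side grade
repartition of a 2008-subject community cohort. One published row
(right-hemisphere C1) does not sum to 100 % in the available text; the
residual mass is assigned to grade 0, the modal typical-anatomy grade.

**Calibration.** `criterion_loading = 0.5` was selected because it
reproduces the published threshold-classified frequencies (left ≈ 21 % vs
printed 22 %, right ≈ 7.5 % vs 8 %). The C0 rule assigns probabilities by
score band — (0.97, 0.03, 0) below 3.5, (0.35, 0.50, 0.15) at 3.5,
(0, 0.26, 0.74) at 4 and above — solved against the published left-side
C0 marginals (70.9 / 11.9 / 17.1 %). Overlap between the C0 = 0 and
C0 = 2 reference classes is confined to the 3.5 band, so the Bayes
boundary — and hence the fitted threshold — always lands at 3.75, the
published value.

**What it does not emulate.** The copula's cross-side dependence acts on
severities, while C0 is drawn independently per side given the score; as a
result the bilateral total-IHI co-occurrence cell reaches ≈ 2.4 % of the
population (vs ≈ 1.1 % under independence), short of the published 4.0 %.
Real bilateral IHI is more concentrated than a shared Gaussian latent can
express. The generator also ignores site/scanner effects, age structure
beyond a narrow band, and any dependence of rater error on severity
(second-rater noise is a uniform adjacent-grade perturbation with
probability ε). Passing tests therefore validate the *analysis machinery*
under realistic marginals and coupling — not the full joint distribution
of a real cohort.

**Sulcal measures.** Cells with a configured effect draw from
group-conditional normals whose means are the published group means and
whose pooled SD is back-computed from the published Cohen's d
(`sd = Δmean / d`); the ipsilateral effect takes precedence for bilateral
IHI when two effects target the same cell. All other cells share a
per-measure baseline with no group difference, on plausible scales
(e.g. opening ≈ 2.5 ± 0.8 mm, GM thickness ≈ 3.6 ± 0.3 mm).

## Numerical choices and degenerate inputs

* Grades are validated against each criterion's grid at every entry point;
  off-grid values are rejected with row numbers when reading CSV.
* Grades are serialised as decimal strings on the 0.5 grid, so a
  write/read round trip is bit-exact.
* Threshold candidates are midpoints of *observed* scores only; fitting
  fails loudly when only one C0 class or one distinct score is present.
* Kappa is undefined when chance agreement is 1 (both raters constant on
  the same category) and errors rather than returning 0/0.
* Zero pooled variance in a t-test yields t = 0 (equal means) or a signed
  infinite-t flag (unequal means).
* Chi-squared tests refuse tables with a zero marginal.
* All simulation is seeded; pipeline outputs (including the provenance
  JSON, which deliberately omits timestamps) are byte-identical across
  runs with the same seed.

## Problem sizes used by the test suite

The suite exercises marginal recovery at n = 5000 subjects, threshold
recovery at n = 1000 subjects across multiple seeds, type-I calibration of
the t-test over 1000 null replicates, and effect recovery on cohorts of
1705 subjects (the size of a typical sulcal-morphometry subset) restricted
to the sulci carrying configured effects. These sizes give Monte-Carlo
error comfortably inside the asserted bands while keeping a full test run
under a minute.

## Known limitations

* The geometric adapters quantify a scale that was designed for visual
  application; their bins have no published calibration.
* Wald intervals undercover for proportions near 0 or 1; use Wilson for
  small counts.
* The independent-samples left-vs-right test ignores pairing (kept for
  comparability; the Stuart–Maxwell variant is the correct paired test).
* Published t/d pairs for sulcal effects are mutually inconsistent under a
  single shared n (per-cell effective sample sizes were not published), so
  exact reproduction of those tables is impossible in principle; the
  package instead verifies recovery of the configured effects on synthetic
  cohorts.
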