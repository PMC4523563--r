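---
title: "Recalibrating a length-based pediatric weight estimation tape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recalibrating a length-based pediatric weight estimation tape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedtape)
```

## The model

A length-based tape partitions supine height into nine ordered color zones,
each carrying a weight range; the predicted weight read off at height $h$
serves as the dosing weight in emergencies. For a child with actual weight
$A$ and tape prediction $B$, the package works throughout with the directed
percent difference

$$d = 100\,\frac{B - A}{A},$$

positive when the tape overestimates. Two facts drive the whole analysis:

1. **Scaling is exact.** If every prediction is scaled by $(1-f)$, each
   child's percent difference transforms as $d' = (1-f)\,d - 100f$, so zone
   means transform the same way and SDs scale by $(1-f)$. No refitting is
   needed to know what a percent correction does.
2. **Zone agreement is a diagnostic problem.** For each zone, "condition
   positive" is *actual weight inside the zone's weight range* and "test
   positive" is *height assigned to the zone*, giving a one-vs-rest 2×2
   table per zone, hence sensitivity, specificity, Cohen's kappa
   $\kappa = (p_o - p_e)/(1 - p_e)$, and a Pearson chi-square (1 df, no
   continuity correction — the choice is conventional and is cross-checked
   against `stats::chisq.test(correct = FALSE)` in the tests).

The correction factor is the overall mean percent difference truncated
toward zero to an integer percent (8.49% becomes 8%): truncation, not
rounding, deliberately under-corrects rather than over-corrects a dosing
weight.

## Interval conventions

All zone intervals are half-open $[\mathrm{lo}, \mathrm{hi})$ with the last
zone closed at the top. Printed range edges such as "64.99" or "8.49" are
canonicalized to exclusive bounds (65, 8.5), which turns printed contiguous
ranges into a true partition; where one boundary is printed as belonging to
two adjacent zones (66.5 cm on the Broselow tape), the half-open rule
assigns it to the upper zone. The printed Broselow *weight* ranges
(3–5, 6–7, ...) genuinely leave gaps; a weight falling in a gap is
unclassifiable and counts as condition-negative for every zone. The IPWET's
operative weight bins are its half-kg classification bins
($<6.5$, $6.5$–$8.5$, ...); its printed integer ranges are display labels.
One printed IPWET bin edge (orange "24.4") is inconsistent with the
adjacent bins and is read as 24.5 so the partition closes.

Within a zone, the tape's per-centimeter weight is modeled as linear
interpolation between the zone's weight endpoints, rounded to the 0.1 kg
resolution of the printed tape. Published zone-level statistics depend on
this choice only through zone means; the rounding produces the ±0.01
discrepancies visible when closed-form corrected means are compared with
per-child recomputation.

## The recalibration pipeline

`build_ipwet()` chains four stages, each auditable in the returned log:

1. **Correction factor** — truncated integer percent of the cohort's mean
   percent difference.
2. **Height re-binning** — per zone, the normal-approximation interval
   $\bar h \pm z_{0.975}\, s/\sqrt{n}$ of measured heights of the children
   the tape assigns there. Intervals of *means* are narrow and leave gaps,
   so each interior boundary is bridged to the midpoint between adjacent
   interval edges, and the outer boundaries extend to the cohort's observed
   height range rounded outward to whole cm. The midpoint bridge is this
   package's reconstruction — interval estimation alone cannot produce
   contiguous ranges — and every raw interval is kept in the audit.
3. **Height–weight regression** — an ordinary least-squares polynomial of
   weight on height (a univariate Gaussian GLM with identity link). The
   pipeline default is degree 3. A straight line was considered and
   rejected: weight-for-height is convex over a 46–146.5 cm span (zone
   weight increments grow from ~2 kg to ~6 kg), so a line systematically
   undershoots both ends — on realistic cohorts it extrapolates to
   non-positive weights at the shortest heights and places the top zones'
   ranges well below the weights of the children in them, and tapes rebuilt
   from it *reduce* zone agreement relative to the uncorrected tape. The
   cubic tracks the curvature, and rebuilt tapes then dominate the base
   tape's pooled sensitivity consistently. `fit_height_weight_regression()`
   defaults to degree 1 for the familiar slope/intercept/$R^2$ summary.
4. **Weight ranges** — the fitted curve evaluated at each height boundary,
   snapped to the half-kg grid (lower bound to nearest 0.5 kg, upper bound
   = next zone's lower bound; increments must stay strictly positive or the
   stage errors). Where the curve's lowest boundary value falls below the
   grid, the first bound is floored at 0.5 kg; the clamp is flagged in the
   audit.

The validation sample size is reconstructed as a two-proportion power
calculation (`stats::power.prop.test`): detecting an absolute improvement
of 0.25 over a baseline per-zone sensitivity of 2/3 at $\alpha = 0.05$ and
power 0.80 gives 41 children per zone, 369 over nine zones; children are
conceptually restricted to the middle 60% of each zone (20% trimmed each
side), the band where zone membership is unambiguous. The published design
quotes a minimum of 40 per zone and 360 total; the exact effect size behind
it is unstated, so these defaults are an explicit, documented
parametrization, not a derivation.

## The synthetic cohort generator

The generator's job is to emulate the derivation cohort's *statistical
structure*, not pediatric growth:

- Heights come from a normal distribution truncated to the reference tape's
  range. Defaults target mean 96.64 cm, SD 26.06 cm. Because truncation
  shrinks the SD (to ~22.5 if one naively truncates an SD-26.06 normal to
  46–146.5 cm) and the exclusion rules further thin the tallest children,
  the parent parameters are solved numerically so the *realized* mean and
  SD match the configured targets.
- Each child's weight is $A = B(h)/(1+\delta)$ with
  $\delta \sim N(\mu_\delta, \sigma_\delta)$, which makes the tape's
  relative overestimation equal $\delta$ by construction — the injected
  bias is exact, so correction-factor recovery tests are sharp. Defaults
  $\mu_\delta = 0.0849$, $\sigma_\delta = 0.1459$ reproduce the derivation
  study's mean percent difference (8.49, SD 14.59) and yield a
  height–weight correlation near 0.95 (the study reports 0.954).
- The weight exclusion ($A > 36$ kg) corresponds to
  $\delta < B/36 - 1$; rejecting only those draws would left-truncate
  $\delta$ for tall children and inflate the realized mean bias. The
  admissible window is therefore mirrored about $\mu_\delta$
  — symmetric truncation preserves the mean exactly — and rejected records
  are regenerated until exactly $n$ survive.
- Age is back-filled from height by inverting a piecewise-linear
  height-for-age curve anchored at (1 mo, 54 cm), (12 mo, 75 cm),
  (60 mo, 109 cm), (144 mo, 149 cm) plus noise (SD 4 months), clamped to
  1–144 months. The anchors are plumbing: age enters no published
  statistic beyond descriptives.
- Heights are recorded to 0.1 cm and weights to 0.1 kg, mirroring
  measurement resolution. A single PRNG stream seeded from the config makes
  cohorts byte-reproducible.

What the generator does **not** emulate: the bimodal clinic mix of real
outpatient height distributions (a single truncated normal is used),
sex-specific growth, malnutrition subgroups, and measurement error beyond
resolution rounding. Tests passing on these cohorts therefore demonstrate
the *pipeline's* correctness and the *structural* behavior of
recalibration, not the exact zone statistics of any real population —
reproducing a specific study's per-zone sensitivities or exact rebuilt
boundaries would require its raw data.

## Numerical choices

- Sample SDs use the $n-1$ denominator; a single-child zone reports SD 0
  with a degeneracy flag rather than `NA`.
- Rounding is half-away-from-zero on the target grid (0.1 kg predictions,
  0.5 kg derived bounds); display rounding is 2 decimals, with p-values
  floored at "<0.0005" in rendered reports. All internal computation is
  full precision.
- Paired t-tests compare measured vs predicted weights within a zone (the
  same children measured two ways); zones with fewer than 2 children, or a
  degenerate difference vector, report `NA`.
- Diagnostic metrics with an empty margin are reported `NA` (undefined),
  never as propagated `NaN`.
- The correction factor is restricted to 0–50%: a negative raw mean of
  magnitude ≥ 1% (a tape that *under*estimates) is outside this tool's
  calibration direction and errors rather than silently inflating weights.

## Test problem sizes

The property suite runs the generator at $n = 10{,}000$ over 20 fixed seeds
for factor recovery and the rebuilt-vs-base sensitivity comparison, 100
parameter-fuzzed cohorts of 500–900 children for partition validity, and an
exhaustive sweep of all 2×2 tables with $N \le 40$ for the kappa oracle —
sizes chosen so every stochastic check is comfortably away from its
decision boundary while the whole suite stays fast.

## Known limitations

- The midpoint bridging of interval gaps and the sample-size parametrization
  are reconstructions of under-specified published procedures; both are
  flagged in audits and documented here.
- Rebuilt weight bins are contiguous half-kg bins; a population whose
  weight-for-height spread is very tight would be better served by finer
  grids (the snapping unit is fixed).
- The improvement guarantee is about *pooled zone-match sensitivity*;
  individual zones (especially narrow interior ones) can lose sensitivity
  even when the pooled rate improves.
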