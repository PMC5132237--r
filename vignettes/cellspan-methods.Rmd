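---
title: "Methods: single-cell replicative aging analysis with cellspan"
author: "cellspan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell replicative aging analysis with cellspan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellspan)
```

## The data model

Budding yeast divides asymmetrically: a mother cell buds off age-reset
daughters until, after a limited number of divisions — its replicative
lifespan (RLS) — it dies. Followed individually in a microfluidic device, a
mother cell yields a *life history*: at every replicative age $k$ (the
unbudded G1 directly before the $k$-th budding event) one records the
cross-sectional area $s_k$ (µm²), the elapsed time $t_k$ (hours, with
$t_1 = 0$ at the first observed G1) and, when a fluorescent reporter is
tracked, the background-corrected average intensity $c_k$ (AU). The death
frame is excluded, so a series of length $K$ corresponds to $K$ completed
divisions and the RLS is simply $K$ for a death-observed cell. Only
trailing missingness is legal in the wide input tables — an interior gap
indicates a curation error and is rejected, naming the cell.

Average intensity is a concentration proxy; the product $c_k \cdot s_k$
proxies the total reporter amount in the cell. Censored cells (washed out
before death) are carried with `death_observed = FALSE` and handled by the
survival estimator, but curated cohorts normally contain only full
lifespans.

## Trajectory smoothing

Per-cell series are short (median ~16 points) and noisy, so each series is
smoothed with a natural cubic smoothing spline: the minimiser of

$$\sum_{k=1}^{K}\big(y_k - f(x_k)\big)^2 \;+\;
  \lambda \int f''(t)^2\,dt ,$$

solved exactly by the Reinsch algorithm with knots at the data. The
smoothing strength uses the R `spar` convention: abscissae are rescaled to
$[0,1]$ and $\lambda = r\cdot 256^{3\,\mathrm{spar}-1}$ with trace ratio
$r = n/\mathrm{tr}(K)$, $K$ the roughness matrix. The default
`spar = 0.5` is the conventional strength for these longitudinal profiles.
Two properties anchor correctness: any affine series is reproduced exactly
(a line has zero roughness) and the fitted values are linear in the input;
the test suite checks both, plus agreement to $10^{-6}$ with an
independently coded dense smoother-matrix solve. Fitted values from R's
`smooth.spline(..., all.knots = TRUE)` at the same `spar` agree closely but
not bit-exactly: its Fortran internals scale $\lambda$ through a B-spline
basis whose trace ratio differs slightly from the exact natural-spline one.
For this reason every statistic that depends on the smoother should be
read with a small tolerance (±0.05 on fold values) when compared across
implementations.

Series with fewer than 4 points are returned unchanged and flagged
unfitted. Raw sizes are used for the start-size and end-size correlations
(assessed before any fitting); fitted sizes are used for fold-increase
values, SEP sizes and the concentration analyses.

## Senescence Entry Point

Late in life division durations lengthen abruptly; the onset is the
Senescence Entry Point (SEP). `detect_sep()` formalises the visual elbow
call on the profile of durations $d_a = t_{a+1} - t_a$ against age $a$:
both axes are rescaled to the unit square (hours and divisions are
incommensurable), and the SEP is the interior point with the largest
perpendicular distance to the chord joining the first and last points, on
the side the curve sags towards — durations stay flat and then rise, so
the pre-senescent plateau lies below the chord. Ties break to the earliest
age; if no point clears the chord by more than `epsilon = 0.02` (in
rescaled units) no SEP is called. The detected age is therefore the *last
normally-paced division*; the first slowed division is the next age.
Profiles shorter than 3 durations cannot carry an elbow, and cells with
fewer than 4 recorded ages are excluded from SEP-conditional analyses
(`sep_status = "too_short"`).

Design notes, where the choice was genuinely open:

* **Raw versus smoothed profiles.** The elbow is called on raw durations
  by default. Smoothing the profile first (`sep_on_fitted = TRUE`) sounds
  attractive but measurably *worsens* ground-truth recovery on synthetic
  cohorts (~0.70 versus ~0.73–0.81 of cells within ±1 division), because
  the smoother rounds off exactly the corner being sought.
* **Side restriction.** Limiting the search to the sagging side prevents a
  deep single-frame dip *above* the chord (a transiently fast division)
  from being called senescence.
* **Known limitation.** With realistic duration jitter (multiplicative,
  sdlog 0.15) and 20-minute frame quantisation, a single below-chord dip
  before the true elbow occasionally wins the maximum-distance search; on
  synthetic cohorts roughly a fifth of calls land 2–3 divisions early.
  The detector is exactly equivalent to exhaustive distance search — this
  is a property of the chord criterion itself on noisy quantised profiles,
  and one reason SEP-dependent statistics carry wide tolerances.

## Population statistics

* **Per-age correlation screen.** At each age $a$, the feature of every
  cell alive at $a$ (fold-increase $s^{fit}_a/s^{fit}_1$ by default) is
  Pearson-correlated with eventual RLS. Ages with fewer than `min_n = 10`
  cells are omitted (the cutoff is a reporting choice, not an inference
  rule). Optionally all post-SEP points are excluded at each age, which
  isolates the pre-senescent signal from the terminal enlargement burst.
  No multiple-testing adjustment is applied across ages: the series is
  descriptive, and is read as a trend, not as a family of tests.
* **Median split and survival.** Cells alive at the split age (default 5,
  an age before any mortality in the cohorts this mirrors) are split at
  the population median of fold-increase; the tie rule is strictly-below
  versus at-or-above. Lifespans of the two groups are compared with
  Kaplan-Meier curves and the two-group log-rank test (1-df chi-square,
  no continuity correction). The KM median is the smallest age at which
  survival reaches 0.5 or below; without censoring this equals the
  (lower) sample median. Group medians are summarised as
  `round(100 * (med_less - med_more) / med_more)` percent.
* **Rank-sum comparisons.** Distribution shifts (e.g. hours to reach age
  5 in the two split groups) use the two-sided Wilcoxon/Mann-Whitney
  test: for $n+m \le 10$ the exact permutation distribution of $U$ is
  enumerated (mid-rank scoring under ties); otherwise the tie-corrected
  normal approximation with continuity correction.
* **Reporter accounting.** Concentration analyses use spline-fitted
  average intensity; total amount is intensity × area. The
  concentration-size relation at a given age is the cross-sectional
  Pearson correlation and OLS slope over cells alive at that age; the
  conditional screen repeats the per-age correlation on subsets of cells
  reaching at least a given RLS.

## The synthetic cohort generator

`generate_population()` produces cohorts with the statistical structure
the analysis assumes, with known per-cell ground truth, so every stage of
the pipeline can be tested without external data. Per cell $i$:

* growth rate $g_i \sim \mathrm{LogN}$ (median 0.6 µm²/h, sdlog 0.35) and
  base cycle $\tau_i \sim \mathrm{LogN}$ (median 1.5 h, sdlog 0.2) — a
  mid-exponential budding cell divides every 1.5–2 h, and areas grow by a
  few µm² per hour;
* starting area $s_i \sim \mathrm{LogN}$ (median 17.65 µm², sdlog 0.18),
  matching the observed population median and spread;
* lifespan $L_i$ from a discretised log-normal (median 16 divisions,
  sdlog 0.3, floor 3 so every cell supports fitting), whose log-median
  decreases by $\kappa\,(\log g_i\tau_i - \overline{\log g\tau})$ with
  $\kappa = 0.2$: cells that add more area per division live shorter.
  Because the coupling acts through $g\tau$ and not size itself, the
  start-size/lifespan correlation stays near zero by construction;
* SEP at $\mathrm{round}(0.8\,L_i)$ (senescence occupies the last fifth
  of life); divisions after the SEP age lengthen by 1.4× each, so the
  recorded SEP age is the elbow of the duration profile in the same
  convention as the detector;
* division durations $\tau_i$ with multiplicative jitter (sdlog 0.15),
  snapped to the 20-minute imaging grid; sizes $s_i + g_i t_k$ plus
  0.5 µm² noise — growth is linear in time, so the slowed post-SEP cycles
  automatically produce the late-life per-division enlargement burst (an
  exponential-growth mode exists but is off by default, since observed
  per-cell enlargement is close to constant in time);
* reporter concentration $p/(1 + \delta(\mathrm{fold}_k - 1))$ plus noise
  ($p = 100$ AU, $\delta = 0.5$, sd 5): concentration dilutes in
  enlarging cells while total amount $c_k s_k$ still rises with age.

What the generator deliberately does **not** emulate: daughter lineages,
mechanistic cell-cycle structure (Start/G1-S), heterogeneous modes of
death, age-dependent *reversal* of the concentration-size correlation
(the dilution coupling is constant over life, so that correlation stays
negative at all ages), measurement dropout, or segmentation artefacts.
Passing tests on synthetic cohorts therefore demonstrate that the
pipeline recovers structure it is pointed at — not that real cohorts
contain that structure.

A seeded cohort is fully deterministic, and `truth_table()` exposes
$(g_i, \tau_i, s_i, L_i, \mathrm{SEP}_i)$ for recovery tests: per-cell OLS
slopes recover $g_i$ within ~2% median relative error at the default
noise, and the monotone response of the age-5 correlation to $\kappa$ is
part of the test suite.

## Numerical choices and degenerate inputs

* Spar→λ mapping as above; trace computed from the banded roughness
  factorisation; all solves are exact dense/banded linear algebra (series
  are short, so numerical cost is irrelevant).
* Median-split threshold ties: a degenerate split (every value equal to
  the threshold) is flagged rather than silently producing an empty group.
* `epsilon = 0.02` for the SEP call: below this rescaled distance an
  elbow is indistinguishable from chord-level noise on a unit square.
* Validation is fail-fast and names the offending cell: mismatched row
  ids, count mismatches between size and time rows, non-increasing times,
  non-positive sizes, interior gaps.
* Round-trip fidelity: wide-table output prints 17 significant digits so
  `read(write(dataset))` is bit-identical.

## Problem sizes used by the test suite

Unit and property tests run on cohorts of 100–500 synthetic cells with
fixed seeds; recovery and calibration checks use 300–1000 cells. These
sizes give stable statistics for cohort-level checks (binomial standard
errors below ~0.03 on coverage-style assertions) while keeping the whole
suite fast; they are the package's registered study conditions, and the
tests deliberately do not re-tune generator parameters or seeds.
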