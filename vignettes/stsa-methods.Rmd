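---
title: "Spatiotemporal survival analysis of movement-trajectory responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal survival analysis of movement-trajectory responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(stsa)
```

## The problem

In a two-alternative forced-choice task such as the N-back, a classical
setup records one number per trial: the response time (RT), plus whether the
response was correct. When the response is instead a continuous hand
movement — for example moving a stimulus to a "Match" or a "non-Match" box
in virtual reality — the whole path of the hand carries information about
the decision as it unfolds: when movement was initiated, hesitations,
movements started in the wrong direction and corrected mid-flight. Mean-RT
ANOVAs compress all of that away, and the trimming they require (to meet
their variance assumptions) discards exactly the slow, hesitant trials in
which the dynamics are most visible.

This package implements a distributional alternative in two layers, plus
the classical chain it is compared against and a synthetic generator that
provides ground truth for testing:

1. **Discrete-time survival analysis (SA)** of completed responses.
2. **Spatiotemporal survival analysis (StSA)** of first-crossing events
   along the movement path.
3. The **ANOVA chain**: outlier trimming, variance diagnostics,
   repeated-measures ANOVA with Greenhouse–Geisser correction, post-hoc
   paired contrasts, and windowed conditional-accuracy inference.
4. A **trajectory generator** with known latent structure.

## Data model and coordinate convention

Trials live in a long-format table (`trial_id`, `participant`, `device`,
`n_back`, `trial_type`, `rt_ms`, `accuracy`); trajectories in a second
table (`trial_id`, `t_ms`, `x_m`). The signed position collapses the two
distances to the response boxes: if $A$ is the distance to the Match box
and $B$ to the non-Match box, `signed_position()` returns $(B - A)/2$, so
$x > 0$ means nearer the Match box for every trial, $x = 0$ is the neutral
start, and $|x|$ at a box equals half the box separation. Correctness is
never baked into $x$; it is derived later from the sign of the movement
and the trial type, which keeps counterbalanced box placements trivial to
undo at load time.

Timestamps are milliseconds from stimulus onset. Unfinished trials
(trajectories that never reach a box) are allowed: they carry no RT and no
final accuracy, take part in occupancy maps and crossing risk sets, and
are simply absent from completed-response survival curves — right-censoring
by design rather than deletion.

Absolute spatial scale is configuration, not fact: the default total
travelled distance is 0.20 m (20 thresholds of 0.01 m) and the default
occupancy range is ±0.404 m, but both are `stsa_grid()` /
`occupancy_grid()` parameters, because recorded setups differ in box
separation and collision geometry.

## Discrete-time survival analysis

Time is divided into left-open, right-closed bins $((k-1)w, kw]$ with
$w = 100$ ms by default; bin 37 is (3600, 3700]. For completed response
times $T$ pooled over a condition:

* hazard $h(t) = P(T = t \mid T \ge t)$ — the probability the response
  lands in bin $t$ given it has not occurred before,
* survivor $S(t) = P(T > t)$,
* conditional accuracy $ca(t) = P(\text{correct} \mid T = t)$.

`estimate_survival()` computes all three by direct counting over every bin
up to the last event — nothing is trimmed or dropped. The 70-bin display
window and the 5 % masking rule (`mask_from()`: the first bin with
$S(t) < .05$) affect plots only. There is no Kaplan–Meier machinery
because every included trial has a complete event time. $ca$ in a bin with
no events is undefined (`NA`), never 0, and plots must break lines there.

Median RT is the linear interpolation of $S$ against **bin upper edges**
at $S = .50$ (`median_rt()`); an exact hit returns that edge. Edges rather
than bin centers are a documented choice — the convention is not forced by
anything — and under heavy censoring the median is reported as undefined
(`NA`) rather than an error.

```{r survival-example}
sc <- estimate_survival(c(150, 150, 250, 350), c(1, 1, 1, 1))
sc$curves[1:4, c("bin", "n_at_risk", "n_events", "h", "S")]
```

## Spatiotemporal survival analysis

StSA treats movement through space as the event process. The total
distance is tiled by 20 incremental thresholds (each a further 5 % of the
distance). For each threshold $k$, the **first** sample at which
$|x| \ge$ threshold is an event (`extract_crossings()`); its direction of
travel scores the segment — moving toward the correct box is correct
*regardless of the trial's final outcome*, so ongoing self-corrections are
visible. Detection is sample-exact with no sub-sample interpolation: at
90 Hz the interpolation gain would be under 12 ms, an order of magnitude
below the 100 ms bin width.

Per spatial row $k$ and time bin $t$ (`stsa_maps()`):

* $H(k,t)$ = events / at-risk, where a trial leaves row $k$'s risk set at
  its first crossing of $k$, or at its last recorded sample if it never
  crosses. Each row is an independent discrete-time hazard, so the row-wise
  product identity $\prod_{i \le t}(1 - H(k,i))$ recovers the fraction not
  yet crossed whenever no recording ends early.
* $CA(k,t)$ = mean directional correctness of the cell's events, undefined
  where the cell is empty.

`scale_maps()` divides every hazard map of a condition set by the single
global maximum, so the maps share a color scale and the global maximum is
exactly 1. The default analysis grid is 20 × 70 = 1400 cells; the
high-resolution occupancy grid (`occupancy()`, Stage-2 style) is
101 × 701 = 70,801 cells of 0.008 m × 10 ms. The stated ±0.4 m / 0–7 s
ranges do not divide evenly into 101 × 701, so the defaults realize the
bin counts with ranges −0.404..0.404 m and (0, 7010] ms; a sample at
exactly $t = 0$ is assigned to the first temporal bin rather than dropped.
Occupancy counts default to per-trajectory visit indicators (a cell counts
a trial once); per-sample counting is kept for diagnostics, and
`log_view()` is the cellwise $\log_{10}(n + 1)$ display transform.

Trials are never trimmed anywhere in this layer, and computation always
runs to the last observed bin — the 70-bin display truncation is cosmetic.

One ambiguity deserves a note: whether a trial that has already completed
its response should remain in the risk set of thresholds it crossed
earlier. We take the standard discrete-hazard reading — a trial exits row
$k$'s risk set at its first crossing of $k$ (or its recording's end) —
because each row is then a well-formed first-passage hazard with an exact
product identity, which the tests exploit.

## The classical chain

`iqr_trim()` (Tukey fences, type-7 quartiles) and `sd_trim()`
(mean ± 2 SD from the input sample) reproduce the usual RT preprocessing,
each reporting counts and the percentage removed *relative to its own
input*, so staged accounting (raw → IQR → SD → error-trial exclusion)
reads off directly. The mean ± 2 SD rule is two-sided by default; a
`one_sided` flag removes only the slow tail for the reading in which only
long RTs are suspect. Two behaviours are worth knowing: with heavy mass at
one value the SD inflates enough that a lone outlier may survive (e.g. in
{0, 0, 0, 0, 10} the upper bound is ≈ 10.94, so 10 is kept), and a second
SD pass can remove *more* than the first on skewed data because the fences
shrink after trimming — trimming is not idempotent.

`rm_anova()` fits balanced repeated-measures and mixed designs via the
classical Error-strata decomposition, reporting per effect $F$, df, $p$,
partial $\eta^2 = SS_e/(SS_e + SS_{err})$, and for every within-effect
with ≥ 2 numerator df a Greenhouse–Geisser $\varepsilon$ estimated from
the effect-specific orthonormal-contrast covariance of the
participant-by-cell means (pooled within between-groups), with the
corrected $p$ alongside. $\varepsilon$ is clamped to its theoretical range
$(1/(L-1), 1]$; a 2-level factor has $\varepsilon = 1$ identically. Error
sums of squares at floating-point noise level (relative to the total SS)
are treated as zero variance: $F$ is reported as `NA` with a warning
rather than a meaningless ratio.

`windowed_ca_anova()` runs the windowed inference: per consecutive
right-closed 500 ms window (0–4 s, 8 windows), a 2 (trial type) × 3
(n-back) repeated-measures ANOVA with the spatial bin as an additional
within-participant measure, on the CA cell table built by
`windowed_ca_table()`. A participant with any empty cell in a window is
excluded from that window and logged. With all 20 thresholds as levels,
early windows would exclude almost everyone (few trials travel far within
500 ms), so `windowed_ca_table()` can pool adjacent thresholds
(`pool_thresholds`); the error term treats spatial bin as a fully crossed
within factor, a documented modelling choice. No correction is applied
across the 8 windows by default (`p_adjust = "holm"` is available).

## The synthetic generator

`generate_dataset()` produces balanced participants × n-back datasets of
~90 Hz trajectories with Match frequency 0.33, built from interpretable
latent components per trial:

* a **shifted-lognormal initiation delay** (the conventional RT shape),
* roughly **constant-speed travel** toward a box at ± total distance,
* **hesitation**: per-sample pause probability with uniform pause
  durations,
* **early match bias**: with probability $q$ the first leg heads toward
  the Match box regardless of the truth,
* **self-correction**: a wrong-way excursion that reverses mid-flight,
* a per-trial **error probability** deciding which box is finally reached.

Per-level defaults make harder levels slower, more hesitant, more biased
and less accurate (e.g. level-1 trials mostly finish under 2 s while
level-3 delays stretch past 4 s with long tails), which mirrors the
qualitative structure of real N-back trajectory data. They were chosen
once as plausible magnitudes and are all configurable; no default encodes
a measured quantity.

Every trial draws from its own RNG substream derived from the root seed
and a deterministic trial counter (a MINSTD-style integer mix), so a
dataset is reproducible regardless of generation order, and the manifest
records every latent draw for recovery tests.

What the generator deliberately does **not** emulate: 3-D kinematics (the
analyses operate on the signed box-axis projection only), biomechanical
smoothness (legs are piecewise-linear), autocorrelated sensor noise,
learning or fatigue across trials, and between-participant parameter
variation beyond the per-level settings. Passing recovery tests therefore
shows the estimators are correct on data satisfying their assumptions —
not that real hand paths satisfy them.

## Numerical choices and degenerate inputs

* Bins are right-closed everywhere (a response at exactly 3700 ms is in
  bin 37; an event at exactly 500 ms is in window 1).
* `bin_index()` rejects $t \le 0$; trajectory timestamps must be strictly
  increasing (shuffled files are sorted on load; surviving violations are
  duplicate stamps and are rejected with the trial named).
* Empty cells propagate as `NA` (CA, ca), never as 0.
* All-zero hazard maps cannot be scaled (error), an empty dataset cannot
  be averaged (error), and heavy censoring makes the median `NA`
  (signaled, not an error).
* Quartiles are type-7 (R default); removal counts depend on this and it
  is therefore fixed and documented.

## Problem sizes used in the tests

The shipped tests run the estimator-vs-oracle comparisons on 100 random
survival datasets (up to 500 trials) and 20 random event sets; recovery
uses 5000 geometric response times, 2000 biased trajectories and 40
noiseless ones; ANOVA calibration uses 500 null tables of 8 participants
and the windowed-power check 25 replicates of 20 participants × 4 spatial
bins. These sizes give stable pass/fail behaviour at a few minutes total;
all are plain arguments, so larger replications are one edit away.

## Limitations

* Pooled (not hierarchical) survival curves: participants with many trials
  weigh more; per-participant splitting is available via `survival_by()`
  but no shrinkage model is provided.
* No parametric hazards, no covariate (Cox-style) regression, no
  time-series modelling of trajectories, and no bootstrap uncertainty for
  the maps.
* The windowed ANOVA treats CA cell means as homoscedastic normal
  responses, which is an approximation for proportions near 0 or 1.
* `rm_anova()` requires complete balanced cells; there is no missing-data
  machinery beyond per-window exclusion.
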