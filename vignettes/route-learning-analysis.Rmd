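---
title: "Measuring configurational knowledge of walked routes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring configurational knowledge of walked routes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogmapr)
```

## The measurement problem

In route-learning experiments a participant walks an unfamiliar route —
here, routes of 450 m with five turns and four designated landmarks — and
their *configurational* knowledge of it is probed with four tasks:

* **Direction estimates.** Imagining standing at one landmark, facing as
  they did when walking, the participant indicates the direction to another
  landmark on a circle whose upward line is the facing direction.  All six
  unordered pairs of the four landmarks are probed; the score is the mean
  absolute angular error in degrees, a circular quantity in $[0, 180]$.
* **Distance estimates.**  Route and straight-line distances between the
  same six landmark pairs, expressed as ratios to a standard distance
  (a 32 m path walked at the start of each session).  Scored as the Pearson
  correlation between estimated and correct distances and as the mean
  estimated/correct ratio.
* **Sketch maps.**  The participant draws the route with its eleven anchor
  points (start, goal, four landmarks, five turns).  Scored by Euclidean
  bidimensional regression against the correct map.
* **Pathway completion and north pointing** (training condition only).
  After walking a short vista-scale path blindfolded, the participant
  returns unguided to the start and points north.  Scored as stop-point
  distance deviation (cm), return-heading angular deviation, and absolute
  north-pointing error (degrees).

The package implements these scores, the bidimensional regression that
underlies the sketch-map score, a Monte Carlo simulation linking the tasks,
the inferential layer used to analyse a two-condition-by-six-session
design, and a seeded generator of complete synthetic experiments.

## Bidimensional regression

Two labelled planar configurations $(x_i)$ and $(y_i)$ (drawn and
reference, as complex numbers) are compared by the least-squares Euclidean
similarity transform $y_i \approx a + b x_i$, with $b$ encoding rotation
and uniform scale and $a$ translation.  After centring both configurations
the slope is closed form,

$$\hat b = \frac{\sum \overline{x_i^c}\, y_i^c}{\sum |x_i^c|^2},$$

and the bidimensional correlation is $r = \sqrt{1 - SSE/SST}$ with $SST$
taken about the reference centroid, so $r \in [0, 1]$ and $r = 1$ exactly
when the drawn configuration is a similarity transform of the reference.
Design choices:

* **Four-parameter Euclidean fit, reflections excluded** by default — the
  standard treatment of sketch maps, where a mirror-image drawing is a
  genuine error.  `allow_reflection = TRUE` fits the indirect similarity as
  a diagnostic.
* **Closed form, not iterative**: deterministic, testable, and exact.  The
  test suite confirms agreement with an independent numerical optimiser to
  $10^{-6}$ relative SSE on noisy configurations.
* **All eleven anchors are weighted equally** in sketch-map scoring; turns
  and terminals are as much a part of the drawn configuration as the
  landmarks.  (Scoring a subset is possible by passing a reduced
  configuration.)
* Anchors missing from a sketch are dropped pairwise with a warning; at
  least three complete pairs are required.

`fit_similarity()` reports the transform taking the *drawn* configuration
onto the *reference*, so a sketch drawn rotated $+37^\circ$ yields a fitted
rotation of $-37^\circ$.

## The sketch-map Monte Carlo simulation

The simulation asks how accurate a sketch map would be if it were drawn
purely from the participant's own distance and direction estimates.
Starting from the first landmark at its true position, each subsequent
landmark (in walking order) is placed at

* a sampled *ratio* of the true straight-line distance from the previously
  placed landmark — normal with the observed mean and SD of the
  straight-line ratio, truncated at 0.01; and
* the true inter-landmark bearing perturbed by a sampled *direction error*
  — normal with the observed mean and SD of the absolute direction error.

Each simulated four-landmark map is scored by `bidim_r()` against the true
landmarks and the mean over iterations (default 1000) is compared with the
observed sketch-map correlations by a one-sample $t$ test on Fisher-z
values.

An absolute error has no sign, so applying the sampled magnitudes needs a
convention.  The default (`sign_convention = "symmetric"`) gives each
magnitude a random sign: an all-positive convention would rotate the whole
chain coherently, and the similarity fit would absorb much of that
rotation, overstating simulated accuracy in a way that depends on route
shape.  The symmetric reading is the conservative one; both are available.
Two further modelling choices were genuinely open: errors perturb
*consecutive* landmark bearings (the chain reading of the construction),
and simulated maps are compared against the four-landmark configuration
only, not all eleven anchors.  Both choices are isolated behind
`simulate_sketch()` if a different reading is wanted.

## The inferential layer

The design is a classic split plot: condition (feedback-only vs training)
between subjects, session (1–6) within.  `mixed_anova()` computes the
balanced decomposition from explicit sums of squares — condition tested
against subjects-within-condition, session and the interaction against the
within residual — with partial $\eta^2 = SS_\text{effect} /
(SS_\text{effect} + SS_\text{error})$ per effect.  Numerical conventions:

* Effects with (numerically) zero SS report $F = 0$, $p = 1$, so degenerate
  all-equal inputs flow through rather than producing 0/0.
* Sphericity is assumed in the reported degrees of freedom, matching the
  uncorrected dfs such as $F(5, 190)$ that this style of study reports; the
  Greenhouse–Geisser $\varepsilon$ is always computed (attribute
  `gg_epsilon`) and can be applied with `sphericity_correction = TRUE`.
* Two-sample tests are pooled-variance (Student), not Welch, reproducing
  $df = n_a + n_b - 2$.
* Correlations are Fisher-z transformed before averaging or testing and
  back-transformed for display.

`trend_contrasts()` tests single-df polynomial trends over sessions using
the classical integer coefficients (for six levels: linear
$-5,-3,-1,1,3,5$; quadratic $5,-1,-4,-4,-1,5$; cubic $-5,7,4,-4,-7,5$).
Each contrast is tested against its own contrast-specific error with
$N - c$ df — the robust repeated-measures convention — because the source
analyses do not state which error term they used; `error = "pooled"`
switches to the omnibus within residual.

## What the synthetic generator emulates

`cohort_spec()` defines the study conditions: 20 participants per
experimental condition over six weekly sessions, plus an average
sense-of-direction comparison group of 20 observed in session 1 only.  The
defaults are calibrated to the magnitudes the package is designed around:

* **Direction errors.**  Angular noise is wrapped-normal.  A participant's
  latent mean absolute error is the condition-session mean (feedback-only
  ≈ 51.6° → 49.8° across sessions; training ≈ 44.6° → 38.6°, a linear
  improvement; average group 27.1°) plus a between-subject offset.  The SD
  that produces a given mean absolute error is obtained by inverting the
  exact wrapped-normal absolute moment map
  (`wrapped_abs_error_moments()`, `direction_sd_for_mean_abs()`), so specs
  are phrased in the reported unit.  Between-subject SDs (16.5°, 11.5°,
  15.8°) were chosen so that, after adding the sampling noise of a mean
  over 36 estimates (closed form from the same moment map), the total
  between-subject SD of the analysed score reproduces the reported 17.7°,
  12.7° and 17.9°.
* **Distance ratios.**  Ratio multipliers drift linearly across sessions
  (route 0.78 → 1.11, straight-line 0.90 → 1.07; the average group sits at
  1.02 and 1.20), with subject-level offsets (SD 0.24 route / 0.34
  straight) and per-estimate noise (SD 0.15) decomposing the printed
  between-subject SDs.
* **Sketch maps.**  True anchors get isotropic jitter (≈ 28 m → 24 m over
  sessions; 21 m for the average group, values set so cohort mean
  bidimensional correlations fall in the reported .90–.95 band for
  450 m routes), a log-normal participant skill multiplier, and a random
  similarity transform standing in for arbitrary page placement — which
  the bidimensional fit must remove.
* **Pathway completion.**  Return walks have a heading error (SD 19.6°
  trial 1, 15.1° trial 2) and a proportional distance error (SD 0.15 /
  0.12) on vista-scale paths with 2.5–6 m segments, producing stop-point
  deviations near the reported ~100–170 cm and heading deviations of
  ~12–16°.

Session-level interpolations are synthetic choices: only condition-level
SDs and first/last-session means are reported for most measures, so the
generator interpolates linearly and labels these values as defaults, not
ground truth.

What the generator does **not** model: learning mechanisms (memory decay,
landmark salience, anchoring of sketches to the first segment), response
strategies, route-specific difficulty, or correlations between a
participant's abilities across tasks.  Passing pipeline tests on this
generator therefore demonstrates that the *measurement and inference
machinery* is correct under the assumed statistical shell, not that the
shell is a complete model of human route learning.

## Problem sizes and numerical conventions

The test suite exercises the pipeline at the study's own scale: 2 × 20
participants × 6 sessions, 1000-iteration simulations (three seeds for the
monotonicity check), 2000 null datasets for the ANOVA type-I calibration,
and 200 replicate experiments for recovery of a planted condition effect
of $d = 0.8$ — recovered within ±0.25 on average, with detection power
within 5 percentage points of the analytic power for that effect and
sample size.  Further conventions:

* Bearings are degrees clockwise from north in $[0, 360)$; coordinates are
  metres in a local planar frame (routes ≤ 1 km need no geodesy).
* Anchors must lie within 0.5 m of the route polyline, accommodating
  hand-digitised geometry.
* A landmark's facing direction defaults to the bearing of the walked
  segment at that anchor — the natural reading of "as encountered", and the
  stated default rather than a hidden assumption.
* The pathway-completion direction deviation compares the taken return
  heading (end → stop) with the correct one (end → start); an alternative
  reading, the start direction as seen from the stop point, is available
  via `direction_method = "start_vector"`.
* Distance-ratio samples in the simulation are floored at 0.01; observed
  correlations are clamped away from ±1 by $10^{-12}$ before Fisher-z so
  noise-free cohorts pass through the analysis unchanged.

## Known limitations

* The mixed ANOVA requires complete balanced data; dropout handling is out
  of scope.
* Bidimensional regression is Euclidean only — no affine or projective
  variants, and no distortion-grid visualisation.
* Route generation is rejection sampling of self-avoiding polylines with
  near-orthogonal turns; it does not ingest real street networks.
* The simulation reproduces the *construction* of simulated sketch maps,
  not any particular published table of values, which would require the
  original route geometry and raw participant data.
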