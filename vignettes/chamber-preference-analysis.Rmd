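---
title: "Quantifying light and temperature preference of laying hens from detection streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying light and temperature preference of laying hens from detection streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chamberpref)
```

## The measurement problem

An environmental preference chamber (EPC) is a set of interconnected,
individually conditioned compartments in which animals move freely through
automatic doors and thereby "vote with their feet" for the environment they
prefer. The setting this package targets is a three-compartment chamber
housing a small flock of laying hens (six by default), each compartment lit
by a different LED color (white, green, red) at equal luminance, with the
whole chamber held at one of three temperatures per experiment: 17 °C
(cold), 24 °C (thermoneutral) or 35 °C (heat stress). Light colors rotate
over compartments in a Latin square so that position and light are not
confounded; each light-by-rotation experiment runs for two days and the full
nine-experiment block is replicated three times (54 days). One overhead
camera per compartment records continuously; analysis uses two 2-hour
windows per day (09:30–11:30 and 15:00–17:00), giving 648 monitored
camera-hours, and 30 fps footage is down-sampled to 15 fps (≈35 million
analyzed frames) because consecutive frames are highly redundant.

An object detector (out of scope here) reduces each frame to bounding boxes,
one per detected bird. This package starts where the detector ends: a CSV
stream of per-frame, per-compartment boxes, and turns it into the two
behavioral measures below plus their statistical comparison.

## The two response variables

**Unrest index.** For consecutive frames of one compartment with detection
centroid sets $F_i$ and $F_{i-1}$,

$$\mathrm{UI}(i, i-1) \;=\; k \cdot \max\!\big(d(F_i, F_{i-1}),\; d(F_{i-1}, F_i)\big),$$

where $d(A,B) = \max_{a \in A} \min_{b \in B} \lVert a - b \rVert$ is the
*directed Hausdorff distance* and $k$ is a camera proportionality factor
(dimensionless, default 1 for the 90° overhead lenses). The defining
notation of the index leaves the set distance $d(\cdot,\cdot)$ ambiguous
(max–min, mean–min and sum–min all exist in the literature); we implement
the directed-Hausdorff (max–min) reading, the only one under which the outer
two-direction $\max$ is meaningful rather than redundant. The index needs no
bird identities — essential, because the detector cannot track individuals.
It is zero iff the centroid sets coincide, symmetric, translation invariant,
and scales linearly with $k$ and with the pixel coordinates; the test suite
checks all of these and equivalence with an exhaustive max–min oracle.

**Permanence time.** Individual dwell times are unobservable without
identities, but their sum is not: with per-frame bird counts $c_f$ and
effective frame rate $r$,

$$T_L \;=\; \frac{1}{r} \sum_{f \in \text{cell } L} c_f$$

is the cumulative bird-seconds attributed to treatment cell $L$. The
defining prose fixes the divisor at the 30 fps capture rate, but the
analyzed streams are 15 fps after down-sampling; dividing by the capture
rate would halve every $T_L$ and make the estimate depend on the decimation
factor. We therefore divide by the *effective* rate of the stream being
summed, which makes $T_L$ exactly invariant to down-sampling of a static
scene (a tested property) and exactly equal to true bird-time on noise-free
data. A per-bird normalization (minutes per bird) is also reported; its
denominator (flock size × replicate-days) is configurable because no
canonical time base exists for it.

## Statistical comparison

The unit of replication is deliberately coarse: window-level means for the
unrest index (one value per 2-h window per compartment) and
replicate-day totals for permanence. Frame pairs 1/15 s apart are massively
autocorrelated; treating them as independent observations would fabricate
degrees of freedom. Treatments are compared with one-way ANOVA across lights
within each temperature, a balanced two-factor ANOVA (light × temperature ×
interaction; unbalanced layouts are rejected rather than silently switching
sum-of-squares conventions), and Tukey HSD at α = 0.05 using the
studentized range distribution (Tukey–Kramer form for unequal n). Pairwise
results are summarized as compact letter displays via insert-and-absorb:
groups sharing a letter are not significantly different, and the sharing
relation is tested to equal the non-significance relation exactly.

Degenerate inputs are flagged, not guessed at: a response with no variation
anywhere yields undefined F ratios (`NA` with a warning); zero within-group
variance with distinct means yields p → 0 pairs.

## The chamber simulator

Real footage and a trained detector are outside desk scale, so validation
rests on an agent-based simulator whose ground truth is known analytically.
Each bird is an independent continuous-time Markov chain on the compartment
adjacency graph (fully connected by default; the true door topology is
configurable). The transition rate from compartment $c$ to neighbor $c'$ is
$r\,w_{c'}$, proportional to the preference weight of the *destination*.
On any symmetric adjacency graph this satisfies detailed balance and gives
stationary occupancy $\pi_c \propto w_c$ — the property parameter-recovery
tests need. `stationary_occupancy()` nevertheless solves the global balance
equations numerically, so the oracle does not assume the closed form. The
rate factor $r$ is calibrated so a bird switches compartments `switch_rate`
times per hour at stationarity. Real hens' switch rates are unreported
anywhere we know of; the default (60/h) is an order-of-magnitude guess and
is labeled as such.

Within a compartment, a bird's centroid performs a reflected Gaussian random
walk (step SD `within_step_px × activity_scale` per frame); birds entering
through a declared door start at that door's edge. The detector model adds
what the analysis must be robust to: isotropic centroid jitter, independent
per-frame misses, and — the empirically dominant artifact — doorway double
detections, where a crossing bird is seen by both cameras at once and one
compartment over-counts by exactly one. Scenario presets (`cold`,
`thermoneutral`, `hot`) mirror the qualitative pattern of interest: strong
white-light preference and normal activity in the cold, flattened preference
and reduced activity under heat stress. They are demonstration settings,
not measurements.

What the simulator does *not* emulate: perch/nest micro-behavior, bird–bird
interactions (agents are independent), realistic body shapes (boxes are
fixed-size), diurnal rhythm within a window, or detector failure modes other
than miss/jitter/double-detection. Passing tests therefore show the
*pipeline arithmetic* is right under the stated noise model, not that the
biological conclusions transfer to any particular henhouse.

## Detector validation arithmetic

The count-level validation protocol compares manually validated frame counts
with predictions: a confusion matrix over counts 0–6, exact-count accuracy
(trace/total, reported to 1 decimal), and the over-count-by-one rate
(superdiagonal/total, 2 decimals). On the reference fixture of 897 frames
with 11 over-by-one errors these are 98.8% and 1.23%. Box-level quality uses
single-class average precision: greedy score-ordered matching at IoU ≥ 0.5
(the conventional threshold; none is stated for the original evaluation) and
all-point interpolation of the precision–recall curve — stated explicitly
because the 11-point convention gives different values on small sets.

Annotation planning uses the finite-population sample size
$n = p(1-p)Z^2N / (\varepsilon^2(N-1) + Z^2p(1-p))$, rounded **up** — a
sample must cover the requested margin. For $N = 35\,\mathrm{M}$, $p = 0.5$,
$\varepsilon = 0.04$ at 99% confidence this gives 1041 frames with the
two-decimal quantile $Z = 2.58$; the three-decimal $Z = 2.576$ gives 1037.
Both quantiles are supported; 2.58 is the default since it reproduces the
published plan of 1041 exactly.

## Numerical and design choices

- **Coordinates.** Continuous pixels, origin top-left, y downward; boxes are
  closed on the min edge, open on the max edge; centroid = arithmetic
  midpoint; frame size 702 × 480 by default, configurable.
- **Empty frames** are explicit records with count 0 — required for $T_L$ to
  be a sum over all frames. For the unrest index, an empty side of a frame
  pair is *missing* by default (absence is not stillness); a `"zero"` policy
  exists for sensitivity analysis.
- **Windows** are half-open $[start, end)$ so boundary frames are never
  double-counted; unrest pairs never span a window gap or a frame-index gap.
- **Duplicate suppression** (`edge_policy`): off by default, matching the
  automatic pipeline whose over-count rate was small enough to disregard;
  when on, door-edge boxes are greedily paired across the door (nearest
  combined edge distance first) and the smaller-area member is removed — a
  proxy for the manual "keep the compartment with the head" rule, whose
  subject is unobservable from boxes.
- **Determinism.** All randomness lives in the simulator and flows from
  explicit seeds; pipeline outputs are pure functions of the run manifest,
  and re-running a manifest is tested to reproduce byte-identical files.
  Input files are processed in lexicographic path order.

## Problem sizes used by the test suite

Simulation-backed checks run at sizes chosen to make Monte-Carlo error
small relative to the asserted tolerances: the occupancy parameter-recovery
experiment uses $10^5$ frames at 15 fps with preference weights
(0.5, 0.3, 0.2) and asserts recovery within ±0.02 of the analytic
stationary law. At hen-scale parameters (6 birds switching ~60 times/h)
the Monte-Carlo standard error of an occupancy fraction over $10^5$ frames
is itself ≈0.02–0.03, so that experiment runs a larger, faster-mixing
synthetic flock (12 birds, 360 switches/h), bringing the standard error to
≈0.006 and making ±0.02 a >3σ band. This is purely a variance-reduction
choice for the Monte-Carlo experiment; the estimator under test is blind to
both parameters, and the simulator's *defaults* keep the hen-scale values.
Null calibration of the Tukey procedure uses 1000 replications of a
3-group × 6-replicate null, asserting a familywise error within three
binomial standard errors of 0.05.

## Known limitations

- The unrest index is a flock-level set distance: one stationary bird and
  one fast bird can score like two moderately active birds; it is a
  screening measure, not a per-animal activity estimate.
- Permanence counts birds, not identities: systematic detector bias (e.g.
  persistent misses under one light color) would bias $T_L$; only unbiased
  noise is validated against.
- The factorial ANOVA is balanced-only by design; real data with lost
  windows must be pooled or analyzed per-temperature.
- The published real-data tables cannot be reproduced here (raw footage and
  trained weights are unavailable); the package reproduces the
  *computations* and validates them on synthetic ground truth instead.
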