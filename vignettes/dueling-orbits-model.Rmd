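---
title: "Modelling the Dueling Orbits induced-motion illusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the Dueling Orbits induced-motion illusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 5)
library(duelingorbits)
```

## The phenomenon and the model

In a dueling-orbits display a small target disc moves on a perfectly
circular orbit while four larger inducer discs, arranged around it, orbit
synchronously on their own circles. Although the target's physical path
never changes, the motion of the inducers radically distorts its *perceived*
path: depending on the inducers' relative phase, speed and direction the
target appears to trace an elongated ellipse, an enlarged circle, a 5-point
star or a triangle.

The package implements a cue-combination account of this illusion. The
visual system has two sources of evidence about the target's trajectory:

* the **eye-centered path** — the target's retinal trajectory corrected by
  an efference copy of the eye movements. With perfect self-motion signals
  this equals the true (world) orbit up to a constant translation;
* the **relative path** — the target's motion relative to the inducers,
  i.e. the difference between the eye-centered displacement of target and
  inducers. Because the inducers move in lockstep this cue is the same
  whichever inducer it is referred to.

The perceived trajectory is modelled as their reliability-weighted average,

$$\mathrm{Perceived}(t) \;=\; k\,\mathrm{EyeCentered}(t) \;+\;
  (1 - k)\,\mathrm{Relative}(t), \qquad k \in [0, 1],$$

applied to displacement vectors about the target's orbit centre. Under the
default veridical pursuit and efference gains this collapses to the
algebraic identity
$\mathrm{Perceived} = d_\mathrm{target} - (1-k)\, d_\mathrm{inducer}$
(displacements from each object's own orbit centre), which the test suite
uses as a brute-force oracle at every sample point.

The weight $k$ captures where the observer's gaze puts reliability: pursuit
of the target makes the eye-centered cue trustworthy ($0.5 < k < 1$),
pursuit of an inducer hands the retinal image to the relative cue
($0 < k < 0.5$), and stable peripheral fixation weighs the cues about
equally. The package defaults are the interval midpoints — 0.5 (fixate),
0.75 (target pursuit), 0.25 (inducer pursuit) — and every entry point
accepts an explicit `k`, or precisions via `k_from_reliabilities()`, for
scenarios (stable frames, central fixation, attentional selection) whose
mechanisms the package deliberately does not model.

## Stimulus conventions and presets

Orbits are parameterised by centre, radius, period, direction and a
starting phase measured in degrees **clockwise from the top** of the orbit,
in mathematical y-up screen coordinates; all lengths are in arbitrary
screen units because the original displays specify none. Six presets encode
the canonical movies: a lone target (movie1); counter-rotating equal-speed
inducers at phase 0 (movie2) and phase 180 (movie3); co-rotating inducers
at phase 180 (movie4); inducers at 1.5 times the target's speed (movie5);
and a target at half the inducers' speed (movie6).

```{r presets}
preset_table()
```

Two preset parameters are not stated in the source material and are fixed
at the unique values that reproduce the published percept shapes, flagged
as `inferred` in the preset provenance: movie4's inducer phase (a
same-direction, same-phase inducer would cancel the relative signal
entirely and predict no illusion, so phase 180 is the only choice that
yields the reported enlarged circle) and movie5/movie6's inducer direction
(kept counter-rotating as in movie2, the only choice producing the 5-lobe
star and 3-lobe triangle). The inducer centres — never specified either —
sit at the four cardinal points of a ring of radius 3 target-orbit radii;
because the relative cue is computed on displacements from each object's
own orbit centre, the model output is invariant to this geometry, and a
test asserts the invariance.

Sampling is half-open over `[0, duration)` at `dt = duration/720` by
default, with the duration equal to the **common repeat period** of target
and inducers (speed ratios must be rational, reduced fraction at most
64/64, or the configuration never repeats). The half-open convention avoids
a duplicated endpoint that would corrupt closed-curve metrics; 720 samples
per repeat resolve even the small corner loops of the inducer-pursuit
triangle (each loop spans well over ten polyline segments), and all shape
metrics are verified to be unchanged at 4x oversampling.

## Viewing conditions

`viewing_condition()` models fixation and smooth pursuit. Pursuit is
zero-lag sinusoidal tracking with a scalar gain $g \in [0,1]$ — the eye
orbits the pursued object's centre at $g$ times its orbital radius — plus
an optional latency that clamps at stimulus onset. The efference copy is
`efference_gain` times the eye's displacement from its starting position.
Defaults are perfect ($g = 1$, efference gain 1): in this model it is the
*weighting*, not the frame arithmetic, that changes with gaze, and the
perceptual effects of imperfect oculomotor signals enter through $k$. Both
gains remain exposed because they are the natural knobs for studying how
pursuit quality should trade off against cue weighting; the frame-closure
identity (eye-centered = world up to translation whenever the efference
gain is 1) is asserted across every preset and condition.

```{r percept, fig.alt = "Cue decomposition for the half-speed-target preset"}
plot_percept(make_preset("movie6"))
```

## Shape metrics

`shape_metrics()` quantifies a predicted (or recorded) percept:

* **lobe count** — strict cyclic local maxima of distance-to-centroid with
  topographic prominence at least 1% of the mean radius. The threshold
  separates true lobes from floating-point ripple on constant-radius paths
  and is exposed as a parameter; 0 lobes means a circle, 2 an ellipse, 3 a
  triangle, 5 a star.
* **aspect ratio and orientation** — principal axes of the second central
  moments of the sample points. For a path traversed uniformly in time as
  $(A \sin \omega t, B \cos \omega t)$ this yields exactly $A/B$, which is
  the quantity the cue weight maps onto; a bounding-box ratio would not
  have this property. Collinear paths (the $k = 0$ limit, where only the
  relative segment remains) report an infinite ratio with the line's
  orientation rather than erroring; paths with a ratio of 1 report
  orientation 0 by convention.
* **self-intersections** — transversal crossings between non-adjacent
  segments of the closed sampled polyline, deduplicated within
  $10^{-9}$ of the mean radius. For the half-speed-target preset the
  crossing count flips from 3 (a loop at each corner) to 0 exactly at
  $k = 0.5$, where the two cue components' speeds are equal and the corner
  degenerates to a cusp.
* **side class** — the path is cut at its lobe maxima into sides; the
  signed perpendicular deviation of each side's midpoint from its chord
  (positive = bulging away from the centroid) classifies sides as convex,
  straight (within 0.5% of the mean radius) or concave, aggregating to
  "mixed" when sides disagree. At equal weighting the triangle's sides are
  *nearly* but not exactly straight — the model predicts a cusped,
  slightly concave deltoid — so no test asserts a class at $k = 0.5$.

For the two elongation presets the model gives the closed form
$\mathrm{AR}(k) = (2 - k)/k$: the perceived ellipse has semi-axes
$(2-k)\,r$ and $k\,r$. This is the invertible link between a percept's
aspect ratio and the cue weight.

```{r metrics}
shape_metrics(predict_percept(make_preset("movie5")))
```

## Recovering the cue weight

`k_from_aspect_ratio()` inverts the closed form, $k = 2/(\mathrm{AR}+1)$,
for quick estimates from reported ellipse shapes. `fit_k()` fits a full
percept trace: after removing the trace centroid and the model's anchor
(translation only — traces are assumed time-locked to the stimulus, as in
a tracing/adjustment task, so no rotation or time alignment is estimated),
the mean squared pointwise distance to the model percept is minimised over
$k$ by a 0.001-step grid search refined by golden-section search to
$10^{-5}$. The 1-D objective is quadratic in $k$, hence smooth and
unimodal, so this simple optimiser is exact for practical purposes; the
grid also provides the diagnostic curve drawn by `autoplot()`.
`bootstrap_ci()` resamples time points with replacement (at least 100
replicates) for a percentile interval, deterministic given a seed.

`simulate_observer()` generates synthetic percept traces — the model
percept for a known `true_k` plus i.i.d. isotropic Gaussian position noise
— for parameter-recovery studies. The noise model is a deliberate
simplification: real tracing data would show temporal autocorrelation and
motor dynamics that the generator does not emulate, so recovery results
certify the estimator's internal consistency, not its behaviour on human
data. At the study conditions used throughout the tests (percepts sampled
at 180 points per repeat period, noise SD 5% of the orbit radius, 100
replicates per cell) the recovery bias stays below 0.02 across every
preset, viewing condition and generating weight in
$\{0.25, 0.5, 0.75\}$, and percentile intervals cover the generating
weight at their nominal rate.

```{r fit}
stim <- make_preset("movie2")
trace <- simulate_observer(stim, true_k = 0.4, noise_sd = 0.05, seed = 42)
fit_k(trace, stim)
```

## Numerical choices and limitations

* Equal target and inducer orbit radii are the default (and the premise of
  the $(2-k)/k$ closed form); both are configurable.
* Problem sizes: shape metrics use the 720-sample default; property sweeps
  and recovery simulations use 180 samples per repeat period, comfortably
  above the 64-per-orbit floor the samplers enforce and enough to leave
  all metrics unchanged under 4x oversampling.
* The self-intersection counter is $O(n^2)$ over segment pairs (chunked to
  bound memory); at the default sampling this is instantaneous, and exact
  crossing counts were cross-checked against an independent computational-
  geometry library during development.
* `k` is a scalar, constant within a trial. Nothing in the framework
  forbids dimension- or time-varying weights, but there is no basis for
  choosing a functional form, so the package does not speculate.
* Phenomena that *change* the weighting — stable frames between target and
  inducers, central fixation, attentional selection between inducer sets —
  are representable only as user-supplied `k` or precision values; the
  package does not model their mechanisms, nor non-circular inducer paths,
  saccades, head movement, or sprite rendering beyond plain discs.
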