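---
title: "Methods: tracking, behavioral metrics, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking, behavioral metrics, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormtracer)
```

`wormtracer` quantifies *C. elegans* locomotor phenotypes from grayscale plate
videos: crawling speed, reversal rate, body-bend rate, and the fraction of
time spent in a coiled posture. This vignette documents the underlying models
and the numerical decisions, in particular where a published description of
this kind of analysis leaves the implementer genuine freedom.

## 1. Image model and segmentation

A frame is a matrix of intensities in [0, 1]; worms are dark, elongated
objects (~1 mm × 80 µm) on a light background under transmitted illumination.
Segmentation is the classical pipeline:

* **Gaussian smoothing**, `sigma = 1` px by default (separable convolution,
  kernel radius 3σ, replicate padding). One pixel is the scale of the camera
  noise and well below the ~3 px body width, so smoothing suppresses noise
  without merging nearby animals.
* **Thresholding**: per-frame Otsu over a 256-bin histogram by default. The
  foreground occupies well under 1% of the frame, so the criterion has a wide
  near-flat plateau between the intensity modes; any threshold on that plateau
  yields the same segmentation, and a `fixed` threshold is available when
  strict frame-to-frame comparability matters.
* **Connectivity**: objects are 8-connected, enclosed background ("holes") is
  4-connected — the standard complementary pair, which makes the hole count of
  a closed loop exactly 1.
* **Size gate**: components outside `[0.25, 2] ×` the expected worm area are
  discarded. The lower bound removes noise specks. The upper bound is chosen
  to remove merged multi-worm blobs: a touching pair renders at ~2.2× the
  single-worm area while a single animal's area varies by well under 2× with
  posture, so 2× cleanly separates the two. (A looser bound that admits
  merged pairs lets tracks link through collision centroids, which inflates
  measured speed and manufactures spurious trajectory bends.) The factors are
  configurable; the expected area comes from the arena calibration
  (`expectedWormArea()`).

**Midlines.** The skeleton (Zhang–Suen thinning) is pruned to its longest
geodesic path, ordered end to end. Thinning erodes roughly half a body width
at the nose and tail, so each endpoint is extended along its local direction
until it leaves the mask. Objects with holes have no simple path and return an
empty midline with a `coiled` flag — exactly the postures the coil detector
handles instead.

## 2. Tracking

Objects in consecutive frames are linked when their centroid displacement is
at most `dMax` (default 3 × the expected per-frame displacement,
`3 · speed_mean / fps`). Per frame pair the assignment maximises the number of
links and then minimises total displacement; the feasibility graph is
decomposed into connected components, each solved exactly by enumeration
(components larger than 8 animals — which only arise in dense clumps — fall
back to greedy nearest pairs). Ties resolve towards lower object ids, making
runs bit-reproducible.

Identity is deliberately *not* guessed through contact: when two animals merge
into one blob, their tracks end and new tracks begin after separation. Gaps
default to 0 frames (strictly consecutive linking) and tracks shorter than 30
frames (10 s at 3 fps) are discarded as uninformative. Instead of manual
track-by-track review, `validateTracks()` applies explicit, logged gates: any
implied speed above `maxSpeed` (default 500 µm/s, several times the fastest
plausible crawl) or frame coverage below 90% of the track's span rejects the
track with a reason code.

## 3. Behavioral metrics

All metrics are computed per track. Cohort summaries report each readout two
ways: the unweighted mean ± SEM across tracks (the per-animal statistic used
in group comparisons) and a pooled, time-weighted estimate (per-step speeds
pooled; events over total observed time; coiled frames over total frames).
Tracks fragment wherever animals touch, and weighting fragments equally
over-weights short, noisy fragments; the pooled estimate is the one
comparable to a frame-weighted ground truth or to the mean of a pooled speed
histogram.

**Centroid smoothing.** Differentiation amplifies segmentation jitter (the
mask boundary fluctuates by a fraction of a pixel frame to frame), so track
centroids are first passed through a 3-frame running mean (`smoothCentroids`,
set 1 to disable). At 3 fps this is a 1 s window, well below the time scale of
crawling manoeuvres.

**Speed** at step *i* is `|c_{i+1} − c_i| · fps` in µm/s; the per-track value
is the mean over steps.

**Reversals.** At each interior point the displacement vectors over
`smoothWindow = 5` frames before and after are compared; an event fires where
their angle exceeds `angleThreshold = 50°`, with one event per contiguous
supra-threshold excursion (the frame of maximal angle), which prevents a
single turn from being counted twice. Points whose windowed displacement is
below `smoothWindow × minStep` (default 0.2 px-equivalent per frame) are
ignored — without this gate, sub-pixel jitter of a stationary animal generates
arbitrary angles. The window length matters more than it looks: a crawling
worm's centroid wobbles at the undulation frequency (period ~3.3 s at 0.3 Hz),
and a window much shorter than half that period lets the wobble masquerade as
>50° bends in slow animals; 5 frames (1.67 s at 3 fps) spans the half-period
and, on simulated video, makes detection on rendered frames agree with
detection on noise-free trajectories. The window and velocity floor are
declared, configurable decisions; the 50° threshold is the field's operational
definition of a reversal. The rate is normalised by total observed track time
(a whole-track "reversals per minute"), not by moving time — the alternative
normalisation is a one-line change but changes the meaning of the rate for
coiler-heavy cohorts.

**Coiled-time fraction.** A frame is coiled iff the object has ≥ 1 hole *and*
its gate speed is at most `vCoil`. The gate speed is the net displacement over
±2 frames divided by the elapsed time: over ~1 s, segmentation jitter does not
accumulate while genuine crawling does, separating the two regimes far more
cleanly than frame-to-frame differentiation. `vCoil` defaults to 10% of the
cohort median track speed.

**Body bends.** The midline is resampled to 21 points by arc length; the
signed three-point curvature at the mid-point (lever arm 5 resampled points)
gives one value per frame, oriented consistently over time by matching
endpoints to the previous frame. A bend is a local extremum of this series
whose sign is opposite to the previously counted bend, scored only while the
animal moves (`vMove`, default 20% of the cohort median speed), and the rate
is normalised by moving time. On top of the alternation rule the extremum must
reach `ampFrac = 0.3` of the series' 90th-percentile magnitude: without this
hysteresis, curvature noise near zero would alternate signs freely and inflate
the count. A sinusoidally undulating animal at frequency *f* yields 2·f·60
bends/min, which is how the estimator is validated.

## 4. Assay statistics

Paralysis assays are right-censored event times; `fractionMoving()` reproduces
the per-timepoint "percent still moving" curves and `logrankTest()` the
two-group log-rank chi-square (via `survival::survdiff`; the test suite checks
it against a direct O−E/V tabulation). Convulsion-type proportions use
two-sided Fisher exact tests with an explicit Bonferroni multiplier — the
multiplier is an argument, never inferred, so the correction matches the
family of comparisons the caller actually made. Per-animal measurements (egg
counts, reversal rates) use `groupCompare()`: Welch t-test, or one-/two-way
ANOVA with Bonferroni-adjusted pairwise t-tests.

**Percent rescue** is `(1 − Δ₁/Δ₂)·100` with Δ₁ = r_drug − r_wt and
Δ₂ = r_nodrug − r_wt. The operator placement follows from the statistic's
defining boundary behavior — it must be exactly 0% when the drug changes
nothing (Δ₁ = Δ₂) and exactly 100% when the wild-type rate is restored
(Δ₁ = 0); no other reading of the formula has both properties. The interface
requires all three rates to be solvent-matched because solvents themselves
shift reversal rates appreciably. Δ₂ = 0 (mutant indistinguishable from wild
type without drug) makes the statistic undefined and raises an error rather
than returning a misleading number. The statistic is invariant under adding a
constant to all three rates and under rescaling them, and strictly decreasing
in r_drug whenever the mutant reverses more than wild type.

## 5. The synthetic benchmark

Real plate recordings with per-frame ground truth are essentially unavailable,
so every stage is validated against a simulator whose defaults emulate a
typical rig: 1280 × 1024 px at 27.3 µm/px (a 35 mm dish on the long sensor
axis), 3 fps, 10 min, up to 20 animals.

Each worm is an agent with centroid, heading, undulation phase and a mode
(RUN / REVERSAL / COIL):

* The **body** is a 21-point midline built by integrating a tangent-angle
  profile — a sinusoidal bend along the body for crawling (amplitude set by
  `undulationAmp`, default 125 µm; frequency 0.3 Hz, a typical crawl), a full
  circle of circumference equal to the body length for COIL. Integrating the
  tangent keeps consecutive points exactly equidistant and the arc length
  exactly the body length. The stroke tapers hemispherically at the body ends,
  so the rendered extent equals the body length; coiled loops keep full width
  so the annulus (and its hole) stays intact at the default geometry.
* **Reversal events** are a Poisson process in *absolute* time (default
  2/min): the event clock keeps running during episodes, so the long-run event
  rate equals the configured rate exactly — if events only accrued during RUN,
  the realised rate would be biased low by the episode-time fraction. An event
  flips the heading by 120–180° (uniform, random side); the flip range is a
  modeling choice, as mutant turn-angle distributions are not quantitatively
  described. Events that fire while coiled still count in ground truth even
  though no tracker can see them; at the default ~5% coiled time this is a
  small, known component of the recovery error budget.
* **Coil episodes** (default 0.3/min, mean 10 s) freeze the centroid, heading
  and phase, and curl the midline into a circle centred on the current
  centroid — entry and exit therefore cause no centroid jump and no spurious
  reversal.
* **Boundaries**: inside a one-body-length margin the worm steers gradually
  (15°/s) back towards the interior, as real animals do at the plate edge;
  specular reflection remains as a failsafe. A hard bounce would be an
  instantaneous direction change that the reversal detector would count but
  ground truth would not; gradual steering stays below the 50° detection
  threshold by construction.
* **Camera noise** is additive Gaussian (`noiseSd = 0.02` on the [0, 1]
  scale); illumination is uniform, matching the steady transmitted-light
  geometry of these rigs.

What the generator does **not** emulate: worm–worm contact dynamics (rendered
blobs simply merge), omega turns and other 3-D postures, body-size variation,
background texture from the bacterial lawn, and illumination drift. Passing
the recovery tests therefore demonstrates correctness of the measurement
chain, not robustness to every artifact of real video.

## 6. Problem sizes and reproducibility

All randomness flows through explicit seeds (`withSeed` wraps and restores the
global RNG state), and identical configurations are bit-reproducible,
including rendered frames. The validation suite uses: exact-equality checks of
the reversal detector against a brute-force scan on 100 simulated tracks; one
full-scale end-to-end cohort (20 worms, 10 min, 3 fps, full frame size) for
parameter recovery at its stated tolerances (speed within 10%, reversal rate
within 3 SE of its Poisson rate, coiled fraction within 5 percentage points);
~100 worm-hours of kinematic simulation for Poisson-rate consistency; 1000
replicates for log-rank calibration; and 20 repetitions of wild-type-like vs
mutant-like cohorts (20 animals each, 60 s, 14 mm field) for phenotype
discrimination. Fixture cohorts use a scaled-down field of view at the native
pixel size and frame rate so that geometry-dependent behavior (blob size in
pixels, per-frame displacement) matches the full-scale setting.

## 7. Known limitations

* Identity is lost at every collision by design; per-animal rates in crowded
  fields are computed over track fragments, which slightly reweights cohort
  means towards faster (more collision-prone) animals.
* The coil detector requires the closed loop to enclose at least one
  background pixel after smoothing; extremely tight coils at coarser pixel
  scales would be missed.
* Body-bend counting needs a usable midline in ≥ 80% of frames; heavily
  coiled tracks return `NA` with a flag rather than a rate extrapolated from
  sparse data.
* The log-rank, Fisher and ANOVA layers assume the designs they are standard
  for (two groups, 2×2 tables, roughly homoscedastic groups); no dose-response
  fitting or mixed-effects modeling is provided.
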