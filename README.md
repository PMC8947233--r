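# wormtracer

Automated multi-worm tracking and behavioral phenotyping for *Caenorhabditis
elegans* plate videos, with the statistical layer used in pharmacological
assays on those phenotypes.

## What it does and for whom

Labs that phenotype *C. elegans* locomotion — for example to characterise
movement-disorder models or to screen candidate drugs against them — record
groups of animals crawling on an agar plate with a grayscale camera (commonly
1280 × 1024 px at 3 frames/s for 10 min) and quantify behavior from the video.
`wormtracer` implements that analysis end to end:

1. **segment** — each frame is Gaussian-smoothed and thresholded (Otsu by
   default); dark objects are extracted as 8-connected components and gated by
   size, discarding specks and merged multi-worm blobs. Each object carries its
   centroid, area, count of enclosed holes (4-connected background components),
   and a skeleton midline.
2. **track** — objects are linked across consecutive frames by centroid
   proximity: per frame pair, the assignment maximises the number of links with
   displacement ≤ d_max and, among those, minimises the total displacement.
   Automated quality gates (implausible speed, poor frame coverage) replace
   manual track-by-track inspection.
3. **metrics** — per track:
   - *speed*: v_i = |c_{i+1} − c_i| · fps (µm/s), averaged over steps;
   - *reversals/min*: events where the angle between smoothed pre- and
     post-displacement vectors exceeds 50°, one event per supra-threshold
     excursion;
   - *body bends/min*: sign-alternating extrema of the signed mid-body
     curvature of the midline, counted while the animal moves;
   - *coiled-time fraction*: frames whose object has ≥ 1 hole **and**
     near-zero displacement — the closed-loop "coiler" posture.
4. **assays** — paralysis time courses (percent of animals still moving; two
   group log-rank test), convulsion proportions (Fisher's exact test with
   Bonferroni correction), egg-retention and reversal-rate group comparisons
   (t-test, one-/two-way ANOVA with Bonferroni), and the **percent rescue** of
   a drug on an abnormal reversal rate:

   rescue % = (1 − Δ₁/Δ₂) · 100,  Δ₁ = r_drug − r_wt,  Δ₂ = r_nodrug − r_wt

   where all three rates are solvent-matched reversal rates per minute. The
   statistic is 0% when the drug changes nothing and 100% when it restores the
   wild-type rate.
5. **simulate** — a ground-truthed synthetic plate-video generator: worms are
   agents with a 21-point midline, sinusoidal undulation, Poisson reversal and
   coiling events, rendered dark-on-light with camera noise. Every downstream
   stage is validated against this ground truth, because real recordings with
   per-frame annotations are essentially never available.

## Worked example

```r
library(wormtracer)

cfg <- wormSimConfig(arenaSize = c(512L, 512L), nWorms = 4, duration = 180,
                     speedMean = 60, reversalRate = 3, coilRate = 0.6,
                     coilDurationMean = 10, seed = 42)
res <- runPipeline(pipelineConfig(sim = cfg))
res
#> wormPipelineResult
#>   2094 objects -> 6 accepted tracks (74 orphan objects, 0 rejected tracks)
#>              metric        mean        sem n      pooled
#>          mean_speed 60.87366487 4.45331510 6 64.62624592
#>   reversals_per_min  2.77062057 0.83016457 6  2.94935452
#>  body_bends_per_min 35.32584981 0.73493250 5 35.83485130
#>       coil_fraction  0.08497281 0.06048063 6  0.05247525
```

Four simulated worms crawling for 3 min yield six accepted tracks (tracks
split where animals touch — identity is never guessed through a collision).
`mean`/`sem` are across tracks; `pooled` is the time-weighted cohort
estimate, which is the number comparable to frame-weighted ground truth. The
run recovers the generator's truth closely: realised mean speed 65.5 µm/s
(pooled estimate 64.6), realised reversal rate 2.92/min (estimated 2.95),
undulation 0.3 Hz → 36 bends/min (estimated 35.8), coiled-time fraction
0.055 (estimated 0.052).

The rescue statistic works on any triplet of solvent-matched reversal rates:

```r
percentRescue(rDrug = 3.1, rNoDrug = 5.9, rWt = 1.8)$rescue_pct
#> [1] 68.29268
```

A thin command-line front end is installed with the package
(`system.file("scripts", "wormtracer", package = "wormtracer")`), with
subcommands `simulate`, `run`, `fixtures`, `rescue` and `assay`.

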