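# gridtrack

Grid cells in the entorhinal cortex fire on a hexagonal lattice, and
their population activity leaves a characteristic signature in fMRI: a
6-fold ("hexadirectional") periodicity of the regional signal as a
function of movement direction. `gridtrack` implements the full
analysis pipeline for detecting such grid-like codes in a circular
virtual-reality arena task in which paths are *observed* (another agent
navigates) and then re-traced — together with a synthetic-data module
that generates every input with known ground truth, so each stage of
the pipeline can be validated end to end.

It is written for computational neuroscientists who want a tested,
self-contained reference implementation of the quadrature-GLM grid
analysis: constrained trajectory generation with balanced direction
sampling, behavioural scoring against a permutation chance level,
cross-validated grid-orientation estimation and magnitude testing at
control symmetries, representational-stability metrics, and
saccade-based eye-movement controls.

## The model

For a translation event with direction α the ROI signal amplitude is
modeled as

    A(α) = b + β · cos(n · (α − φ)),   n = 6

with grid orientation φ (defined modulo 360/n degrees) and grid
magnitude β. Orientation is estimated by modulating translation events
with the quadrature pair sin(nα), cos(nα) (GLM1) and taking

    φ̂ = atan2(mean β_sin, mean β_cos) / n

over ROI voxels; the fit is then tested on held-out trials by
modulating their events with cos(n(α − φ̂)) (GLM2), using a 12-fold
leave-one-trial-out regime within each run. The subject-level grid
magnitude is the held-out modulator beta averaged over folds and
voxels, tested against zero one-tailed with a median ± 3 × MAD outlier
rule. Control symmetries n ∈ {4, 5, 7} run through the identical
machinery.

## Worked example

Generate one task run, simulate a directionally modulated entorhinal
time series with known orientation φ = 23°, and recover it:

```r
library(gridtrack)

run <- generateRunPaths(seed = 42)           # 12 trials x 3 segments
ev  <- scheduleEvents(run, seed = 42, includeNavigation = FALSE)
ts  <- simulateRoiBold(ev, groundTruth(phi = 23, amplitude = 1),
                       noiseSpec(whiteSd = 1, ar1 = 0.3),
                       nVoxels = 8, seed = 42)

res <- runCvGridAnalysis(ev, ts, symmetry = 6, condition = "observation")
res
#> GridCVResult: 6-fold symmetry, condition 'observation'
#>   12 CV folds, 8 voxels
#>   subject magnitude: 0.9934
round(foldOrientations(res), 1)
#> 23.0 22.9 22.9 22.9 22.9 23.0 22.9 22.8 22.9 22.8 22.9 22.9
```

The planted orientation is recovered in every fold and the held-out
magnitude is close to the planted amplitude of 1. The same data tested
at a 5-fold control symmetry carries no systematic signal
(`subjectMagnitude` = −0.563 for this seed, centered on 0 across
seeds), and representational stability is perfect for a noiseless-ish
shared orientation:

```r
stabilityAnalysis(ev, ts, 6, condition = "observation")
#> StabilityResult (half split, 8 voxels)
#>   Rayleigh z: 7.993 (halves 7.987 / 7.998)
#>   temporally stable voxels (<= 15 deg): 100.0%
```

Behavioural scoring: a wrapped-Gaussian re-tracing agent with 0.12 rad
angular noise reaches a mean cumulative distance error of 6.65 vm on
this run, far below the random-agent permutation chance level,

```r
runs <- lapply(1:4, function(s) generateRunPaths(seed = 42 + s))
randomAgentChance(runs, nIter = 5000, seed = 42)$chance
#> 39.9  # vm, 5th percentile of the permutation distribution
```

i.e. only 5% of random agents score below ~39–40 vm on these paths.

`runEndToEnd(pipelineConfig(...), seed)` chains all of the above for a
cohort of virtual subjects and returns per-subject and group tables.

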