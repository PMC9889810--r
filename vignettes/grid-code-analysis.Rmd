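---
title: "Detecting hexadirectional grid-like codes in ROI time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hexadirectional grid-like codes in ROI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridtrack)
```

## The model

Entorhinal grid cells fire at the vertices of a hexagonal lattice.
When an agent translates through an open arena, the aggregate activity
of a grid-cell population is expected to depend on the movement
direction $\alpha$ with a 6-fold (hexadirectional) periodicity: firing
is elevated when $\alpha$ is aligned with one of the three grid axes,
which repeat every $60^\circ$. In fMRI, the corresponding signal model
for a translation event is

$$A(\alpha) = b + \beta\,\cos\!\big(n\,(\alpha - \varphi)\big),
\qquad n = 6,$$

where $\varphi \in [0, 360/n)$ is the *grid orientation* (the phase of
the periodicity, defined only modulo $360/n$ degrees), $\beta$ is the
*grid magnitude*, and $b$ a direction-independent event response.
`gridtrack` estimates $\varphi$ and tests $\beta$ from a
volumes-by-voxels ROI time series (`ROITimeSeries`) and a table of
translation events, entirely within this generative model. The same
machinery runs at control symmetries $n \in \{4, 5, 7\}$, which should
carry no signal when the data are truly hexadirectional.

Because $\cos(n(\alpha - \varphi)) = \cos(n\varphi)\cos(n\alpha) +
\sin(n\varphi)\sin(n\alpha)$, the orientation can be estimated
linearly: translation events are parametrically modulated by the
quadrature pair $\sin(n\alpha)$, $\cos(n\alpha)$ (GLM1), and

$$\hat\varphi = \operatorname{atan2}\!\big(\overline{\beta_{\sin}},\,
\overline{\beta_{\cos}}\big) / n,$$

with the means taken over ROI voxels. We use the four-quadrant
arctangent: a single-argument $\arctan(\overline{\beta_1} /
\overline{\beta_2})$ is quadrant-ambiguous and would mis-assign half of
all orientations. `estimateOrientation()` is tested against a
brute-force grid search over $\varphi$ minimizing the cosine-fit
residual.

The orientation fit is then evaluated on *held-out* data (GLM2): events
are modulated by $\cos(n(\alpha - \hat\varphi))$ and the modulator beta
on the held-out events is the magnitude. Cross-validation is
leave-one-trial-out within a run (12 folds for the standard 12-trial
run): orientations are estimated on 11 trials and tested on the
remaining one, and the subject-level magnitude is the mean of the
held-out betas over folds, then voxels (the two averages commute for
complete data, which the tests assert). Estimating and testing on the
same events would be circular — the magnitude at the orientation that
best fits the data is non-negative by construction — so the held-out
beta is the only quantity ever tested against zero.

### The GLM2 design choice

With one modulator per condition there is a genuine design question:
what exactly is "the" held-out beta? We model the run's translation
events of the analysed condition as two boxcar regressors (held-in,
held-out) and give each its own alignment modulator. The held-out
modulator beta is the fold magnitude; the held-in modulator serves as a
covariate so that genuine grid signal in the estimation trials cannot
leak into the test beta through shared baseline and drift terms.
`modulatorScope = "test_only"` drops the covariate. Per-segment
magnitudes default to $m_s = \beta_{\text{fold}}\cos(n(\alpha_s -
\hat\varphi))$ — the segment-resolved reading of the fold beta, in
which smaller misalignment means a stronger grid-like signal — with
`segmentMagnitude = "fold_beta"` as the uniform alternative. These
feed `buildMagnitudeModulatedDesign()` for follow-up analyses that ask
what else in the brain is time-locked to grid-code strength.

Control symmetries deserve one caution. For a *fixed* trial schedule,
the product $\cos(n'(\alpha - \varphi))\cos(6(\alpha -
\varphi_{\text{true}}))$ contains a term driven by the first circular
moment of the realized direction multiset, so a single schedule can
couple a control symmetry $n'$ to a genuine 6-fold code with a stable
sign — simulations that re-use one schedule across seeds can show a
spurious, schedule-specific control-symmetry offset that has nothing
to do with miscalibration. Averaged over schedules the coupling is
centered on zero, which is how the shipped symmetry-specificity checks
are run (and an argument for randomizing schedules across subjects in
task designs).

A numerical consequence of 3-event folds is worth knowing: when the
three held-out directions are congruent modulo $360/n$, the centered
alignment modulator is nearly degenerate and the fold beta is noisy
(occasionally wildly so). We keep the plain fold average — the betas
remain unbiased, and the group-level median-absolute-deviation filter
(`madOutlierFilter()`, exclusion beyond median $\pm 3 \times$ MAD)
absorbs the resulting heavy tails, which is exactly the role such
robust exclusion plays in this analysis tradition. Folds whose mean
quadrature betas are exactly zero have no defined orientation; they
are dropped from the average with a warning.

### Negative grid-like codes

A subtlety worth spelling out: the quadrature estimator cannot return
a "negative orientation". If a region carries a *negative* n-fold code
($\beta < 0$ at orientation $\varphi$), the arctangent locks
$\hat\varphi$ onto $\varphi + 180/n$ — the anti-phase, where the
modulation is positive — and the cross-validated held-out beta comes
out positive. A stationary negative code is therefore
indistinguishable, within this pipeline, from a positive code at the
shifted orientation. The synthetic signature of a negative code is
instead (a) the estimated orientation sitting half a period off the
generative one and (b) a significantly negative magnitude when the
*generative* orientation is tested directly with
`orientationTransferTest()` (no re-estimation). Empirically negative
cross-validated magnitudes, as reported for primary visual cortex in
this literature, thus require some non-stationarity between
estimation and test data rather than a simple sign flip of a
stationary modulation; our stationary generator cannot (and should
not) reproduce them.

## Design-matrix construction

Events are resolved as boxcars on a 0.1 s microtime grid, convolved
with the canonical double-gamma haemodynamic kernel (response delay
6 s, undershoot delay 16 s, dispersions 1, undershoot ratio 1/6,
peak-normalized; `canonicalHrf()` peaks at 5.0 s), and resampled at
volume acquisition midpoints for a repetition time of 2.029 s by
default. Parametric modulators are mean-centered within the events
that carry them before convolution — this removes collinearity with
the condition boxcar while preserving the quadrature phase relation —
and no serial orthogonalization is applied. A discrete-cosine
high-pass basis with a 128 s cutoff and a constant term complete the
design; rotations, standing and delay periods are left unmodeled and
form the implicit baseline together with the fixation periods.
Estimation is OLS by default; `method = "ar1"` prewhitens with a
pooled lag-1 autocorrelation when a noise model closer to fMRI
practice is wanted. Tolerances: closed-form identities are asserted at
$10^{-9}$ relative, GLM recoveries at $10^{-6}$.

## The task generator

The arena is a 60 vm movement circle inside a 90 vm observation
circle; agents walk at 15 vm/s and rotate at 50 deg/s. A run holds 12
trials of 3 chained path segments. Segment directions come from 36
allowed directions at $10^\circ$ resolution, grouped into 6
directional bins; we default to contiguous $60^\circ$ arcs
($[0,60), \ldots, [300,360)$), with mod-$60^\circ$ residue classes
available via `directionScheme(binMode = "residue")`. The balancing
constraints: three distinct bins per trial, each bin used exactly six
times per run, each of the six arena sectors hosting a trial start
exactly twice, and consecutive segment endpoints in sectors neither
identical nor directly adjacent. The sector rule is what enforces the
60 vm minimum segment length (two points at circular sector distance
$\ge 2$ subtend at least $60^\circ$, i.e. a chord of at least
$2 \cdot 60 \cdot \sin 30^\circ = 60$ vm); the diameter caps lengths
at 120 vm, so every segment is walkable in 4–8 s.

Generation is randomized backtracking. From a start angle, the chord
leaving in direction $d$ is unique ($\theta_{\text{end}} = 2(d + 90) -
\theta_{\text{start}}$, taken only when the resulting displacement
direction equals $d$ rather than $d + 180^\circ$), so only the inward
half of the direction circle is feasible at each step and the sector
rule restricts it further to a $90^\circ$ window. A fixed
bin-to-trial schedule drawn up front is therefore frequently
unsatisfiable; instead the generator draws bins per segment from the
remaining per-run bin budget, weighted toward bins with the largest
remaining count so the budget cannot strand, with per-trial retries
and full schedule reshuffles as fallback. All run invariants are
re-validated on the finished object. Start positions sit on the
movement-area circumference (the paths run edge to edge), uniformly
within the scheduled start sector.

Trial timing: 2 s cue, observation block (1.5 s standing lead-in, per
segment a rotation of $|\Delta\text{heading}|/50$ s then a translation
of length$/15$ s, 1.5 s lead-out), jittered delay, a navigation block
mirroring the observation structure, 1 s feedback, jittered delay. The
delays are specified only as "2–7 s with mean 5 s"; a uniform draw
would give 4.5 s, so the default `defaultJitterSampler()` uses discrete
seconds $\{2,\ldots,7\}$ with weights $(0.05, 0.10, 0.20, 0.25, 0.25,
0.15)$, whose mean is exactly 5 s on the stated support. The sampler
is pluggable through `trialTiming()`.

## Behavioural scoring

Re-tracing performance is the cumulative distance error: the mean
Euclidean (chord) distance between the three correct and three visited
segment endpoints, in vm. The chance level comes from a random agent
(`randomAgentChance()`) that picks its endpoints uniformly from the
circumference discretized in $1^\circ$ steps; over 5000 iterations
against the pooled generated paths the 5th percentile of trial-mean
errors is $\approx 39.3$ vm, and the distribution mean approaches the
closed form $4r/\pi \approx 76.39$ vm for uniform chords. Because a
uniformly random endpoint's error distribution does not depend on
where the correct endpoint lies, the chance level is a property of the
geometry alone — a fact the tests exploit. `normalizedAccuracy()`
expresses a single endpoint error as the fraction of random-agent
errors at least as large (1 = perfect, 0.5 = chance median); the
percentile-rank definition is our choice where the original normalized
measure is not spelled out.

## The synthetic-data generator

`simulateRoiBold()` generates exactly what GLM1/GLM2 assume:
event-amplitude modulation $b + \beta\cos(n(\alpha - \varphi_v))$ on
the translation boxcars, the same microtime convolution as the design
(so noiseless recovery is exact by construction and any failure is a
pipeline defect), plus a cosine drift and AR(1)-plus-white noise per
voxel. Voxel-wise orientations $\varphi_v$ can be jittered around the
shared $\varphi$ (wrapped normal, `voxelJitterSd`) to emulate spatial
instability. `simulateAgentRetrace()` perturbs correct endpoints with
wrapped-Gaussian noise (snapped to the $1^\circ$ scoring grid), whose
mean error follows $r\sigma\sqrt{2/\pi}$ for small $\sigma$ and
$4r/\pi$ in the uniform limit. `simulateGaze()` lays planned
saccades (linear ramps) and blinks (pupil dropouts) onto a fixation
trace. What the generator does *not* emulate: continuous-time grid
firing within a segment, head motion, physiological noise spectra,
spatial voxel correlations, or realistic free-viewing gaze. Passing
tests therefore certify the estimator against its own generative
assumptions, not against everything real data can do.

## Stability and gaze controls

`stabilityAnalysis()` splits a run into halves (trials 1–6 / 7–12),
re-estimates voxel-wise orientations per half, and reports spatial
stability as Rayleigh's $z = N\bar R^2$ on the doubled-angle circle
$\theta_v = n\varphi_v$ (no small-sample correction; the exponential
approximation p-value is optional) and temporal stability as the
percentage of voxels whose orientation moves by at most $15^\circ$ in
the $360/n$-wrapped metric. $z$ is invariant to common rotations and
decreases monotonically with planted orientation jitter, as does the
recovered magnitude — the interpretive link between spatial
instability and weak grid codes, tested as a property.

The gaze module applies the pupil rule (samples beyond 1 SD of the
mean pupil size are removed, not interpolated), detects saccades as
contiguous runs where the boxcar-smoothed (5 ms; kept below the
duration criterion so sub-threshold excursions are not smeared past
it) central-difference speed exceeds 6 SD for at least 12 ms, flags
events without a 200 ms
clean pre-saccadic window, and takes the displacement angle as the
saccade direction (the successive-difference reading of "direction"
is ambiguous in the source description; displacement is the default).
`saccadesToEvents()` rebuilds a translation event table from saccade
directions so the identical grid pipeline quantifies
direction-of-gaze periodicity — the control that distinguishes
spatial coding from oculomotor confounds. `aoiCoverage()` reports the
fraction of valid samples inside supplied area-of-interest polygons
(screen projection of 3-D paths is out of scope; polygons are inputs).

## Problem sizes and limitations

The shipped tests and the acceptance script run observation-only
single runs of 12 trials (about 350 volumes at TR 2.029 s) with 2–8
voxels, 12–50 seeds for Monte-Carlo properties and 200 virtual
subjects for the null-calibration check; these sizes keep each suite
in the minutes range on one CPU while leaving every statistical
assertion at conventional power. Known limitations: magnitudes are in
arbitrary units (comparable within, not across, pipelines); 3-event
folds make single-fold betas heavy-tailed (see above); the voxel-wise
variant refits one design per voxel and scales linearly in voxel
count; and group-level findings reported for real human cohorts in
this literature cannot be reproduced here, since they require actual
participant data — the package certifies the machinery, not the
neuroscience.
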