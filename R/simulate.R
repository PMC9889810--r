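#' Ground-truth directional modulation parameters
#'
#' The generative model the analysis assumes: every translation event of
#' direction `alpha` evokes a neural amplitude `eventBaseline +
#' amplitude * cos(n * (alpha - phi))`, with the orientation `phi`
#' defined modulo `360/n`. A voxel-wise circular jitter of `phi` emulates
#' spatially unstable orientation maps.
#'
#' @param phi grid orientation, degrees in `[0, 360/n)`.
#' @param symmetry fold n of the periodicity (default 6).
#' @param amplitude modulation amplitude, signal units (may be negative).
#' @param eventBaseline direction-independent event response amplitude.
#' @param voxelJitterSd circular SD (degrees) of voxel-wise phi jitter.
#' @return An object of class `GroundTruth`.
#' @export
groundTruth <- function(phi = 0, symmetry = 6, amplitude = 1,
                        eventBaseline = 1, voxelJitterSd = 0) {
  stopifnot(symmetry >= 1, phi >= 0, phi < 360 / symmetry,
            voxelJitterSd >= 0)
  structure(list(phi = phi, symmetry = symmetry, amplitude = amplitude,
                 eventBaseline = eventBaseline,
                 voxelJitterSd = voxelJitterSd),
            class = "GroundTruth")
}

#' Noise model for simulated BOLD
#'
#' @param whiteSd innovation SD of the AR(1) noise (0 disables noise).
#' @param ar1 AR(1) coefficient, in (-1, 1).
#' @param driftAmplitude amplitude of an additive cosine drift.
#' @param driftPeriod_s drift period, s (default 300).
#' @return An object of class `NoiseSpec`.
#' @export
noiseSpec <- function(whiteSd = 0, ar1 = 0, driftAmplitude = 0,
                      driftPeriod_s = 300) {
  stopifnot(whiteSd >= 0, abs(ar1) < 1, driftPeriod_s > 0)
  structure(list(whiteSd = whiteSd, ar1 = ar1,
                 driftAmplitude = driftAmplitude,
                 driftPeriod_s = driftPeriod_s),
            class = "NoiseSpec")
}

#' Simulate a directionally modulated ROI BOLD series
#'
#' Generates the voxel time series the grid-code pipeline assumes:
#' translation events evoke neural boxcars whose amplitude carries the
#' n-fold directional modulation of [groundTruth()], convolved with the
#' canonical haemodynamic kernel at microtime resolution and resampled
#' at the repetition time; a cosine drift and AR(1) noise are added per
#' voxel.
#'
#' @param events event table; rows of `conditions` carry the signal.
#' @param truth a [groundTruth()].
#' @param noise a [noiseSpec()].
#' @param tr repetition time, s (default 2.029).
#' @param nVolumes number of volumes; default covers all events plus the
#'   kernel tail.
#' @param nVoxels number of voxels (default 10).
#' @param conditions event conditions that evoke the modulated response
#'   (default both translation conditions).
#' @param seed optional seed.
#' @param microtime microtime resolution, s (default 0.1).
#' @return An [ROITimeSeries-class]; `metadata` records the seed, the
#'   ground truth and the realized voxel-wise orientations.
#' @examples
#' run <- generateRunPaths(seed = 2)
#' ev <- scheduleEvents(run, seed = 2, includeNavigation = FALSE)
#' ts <- simulateRoiBold(ev, groundTruth(phi = 23), noiseSpec(),
#'                       nVoxels = 2, seed = 2)
#' @export
simulateRoiBold <- function(events, truth = groundTruth(),
                            noise = noiseSpec(), tr = 2.029,
                            nVolumes = NULL, nVoxels = 10,
                            conditions = translationConditions(),
                            seed = NULL, microtime = 0.1) {
  validateEventTable(events)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nVolumes)) nVolumes <- ceiling(eventsDuration(events) / tr)
  total <- nVolumes * tr
  if (any(events$onset + events$duration > total))
    stop("event extends past the end of the series")
  n <- truth$symmetry
  voxelPhi <- wrapFundamental(
    truth$phi + stats::rnorm(nVoxels, 0, truth$voxelJitterSd), n)

  hrf <- canonicalHrf(dt = microtime)
  nSamples <- ceiling(total / microtime) + length(hrf)
  volumeIdx <- pmin(nSamples,
                    floor(((seq_len(nVolumes) - 0.5) * tr) / microtime) + 1L)
  rows <- events[events$condition %in% conditions, , drop = FALSE]

  signal <- vapply(seq_len(nVoxels), function(v) {
    amp <- truth$eventBaseline + truth$amplitude *
      cos(n * degToRad(rows$direction - voxelPhi[v]))
    x <- microtimeBoxcar(rows$onset, rows$duration, amp, nSamples,
                         microtime)
    convolveResample(x, hrf, volumeIdx, microtime)
  }, numeric(nVolumes))

  tVol <- (seq_len(nVolumes) - 0.5) * tr
  drift <- noise$driftAmplitude * cos(2 * pi * tVol / noise$driftPeriod_s)
  if (noise$whiteSd > 0) {
    eps <- vapply(seq_len(nVoxels), function(v) {
      innov <- stats::rnorm(nVolumes, 0, noise$whiteSd)
      as.numeric(stats::filter(innov, noise$ar1, method = "recursive",
                               init = stats::rnorm(1) * noise$whiteSd /
                                 sqrt(1 - noise$ar1^2)))
    }, numeric(nVolumes))
    signal <- signal + eps
  }
  ROITimeSeries(signal + drift, tr = tr,
                metadata = list(seed = seed, truth = truth,
                                voxelPhi = voxelPhi, noise = noise))
}

#' Simulate a noisy re-tracing agent
#'
#' Perturbs each correct segment endpoint of a run by independent
#' wrapped-Gaussian angular noise, snaps responses to the 1-degree
#' scoring grid, and scores each trial with
#' [cumulativeDistanceError()].
#'
#' @param run a `RunSchedule`.
#' @param angularNoiseSd angular noise SD in radians.
#' @param seed optional seed.
#' @param snapStep response snapping step, degrees (default 1; 0
#'   disables snapping).
#' @return list with `responses` (12 x 3 endpoint angles), `errors`
#'   (per-trial vm), `meanError`.
#' @export
simulateAgentRetrace <- function(run, angularNoiseSd = 0.2, seed = NULL,
                                 snapStep = 1) {
  if (!is.null(seed)) set.seed(seed)
  correct <- trialEndpoints(run)
  noiseDeg <- stats::rnorm(length(correct), 0,
                           angularNoiseSd * 180 / pi)
  resp <- wrapDegrees(correct + noiseDeg)
  if (snapStep > 0) resp <- wrapDegrees(round(resp / snapStep) * snapStep)
  radius <- run$arena$movementRadius
  errors <- vapply(seq_len(nrow(correct)), function(i)
    cumulativeDistanceError(correct[i, ], resp[i, ], radius),
    numeric(1))
  list(responses = resp, errors = errors, meanError = mean(errors))
}

#' Simulate a gaze trace with planted saccades and blinks
#'
#' Piecewise-fixation gaze at a constant position, displaced by linear
#' ramps at the planned saccades; planned blinks drop the pupil signal
#' to zero. Ground truth is returned for detector recovery tests.
#'
#' @param duration_s trace duration, s.
#' @param fs sampling rate, Hz (default 1000).
#' @param saccades data.frame with columns onset (s), duration (s),
#'   amplitude (screen units), direction (degrees).
#' @param blinks data.frame with columns onset (s), duration (s).
#' @param noiseSd white positional noise SD, screen units.
#' @param pupilMean,pupilSd pupil baseline level and noise SD.
#' @param start initial gaze position, length-2 numeric.
#' @param seed optional seed.
#' @return list with `trace` (data.frame t, x, y, pupil; attribute `fs`)
#'   and `truth` (the planned saccades and blinks).
#' @export
simulateGaze <- function(duration_s, fs = 1000,
                         saccades = NULL, blinks = NULL, noiseSd = 0,
                         pupilMean = 1000, pupilSd = 1,
                         start = c(0, 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nS <- round(duration_s * fs)
  t <- (seq_len(nS) - 1) / fs
  x <- rep(start[1], nS)
  y <- rep(start[2], nS)
  if (!is.null(saccades) && nrow(saccades)) {
    ends <- saccades$onset + saccades$duration
    ord <- order(saccades$onset)
    if (any(saccades$onset[ord][-1] < ends[ord][-nrow(saccades)]))
      stop("planned saccades overlap")
    if (any(ends > duration_s)) stop("planned saccade exceeds duration")
    for (i in seq_len(nrow(saccades))) {
      a <- which(t >= saccades$onset[i] & t < ends[i])
      dx <- saccades$amplitude[i] * cos(degToRad(saccades$direction[i]))
      dy <- saccades$amplitude[i] * sin(degToRad(saccades$direction[i]))
      ramp <- seq_along(a) / length(a)
      x[a] <- x[a] + dx * ramp
      y[a] <- y[a] + dy * ramp
      after <- seq_len(nS) > max(a)
      x[after] <- x[after] + dx
      y[after] <- y[after] + dy
    }
  }
  if (noiseSd > 0) {
    x <- x + stats::rnorm(nS, 0, noiseSd)
    y <- y + stats::rnorm(nS, 0, noiseSd)
  }
  pupil <- pupilMean + stats::rnorm(nS, 0, pupilSd)
  if (!is.null(blinks) && nrow(blinks)) {
    if (any(blinks$onset + blinks$duration > duration_s))
      stop("planned blink exceeds duration")
    for (i in seq_len(nrow(blinks)))
      pupil[t >= blinks$onset[i] &
              t < blinks$onset[i] + blinks$duration[i]] <- 0
  }
  trace <- data.frame(t = t, x = x, y = y, pupil = pupil)
  attr(trace, "fs") <- fs
  list(trace = trace,
       truth = list(saccades = saccades, blinks = blinks))
}
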