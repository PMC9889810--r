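#' Blink removal from a gaze trace
#'
#' Marks samples whose pupil size deviates more than `k` standard
#' deviations from the mean across the whole recording as invalid
#' (blinks and dropouts are excluded, not interpolated).
#'
#' @param trace data.frame with columns t, x, y, pupil (attribute `fs`).
#' @param k SD multiple (default 1).
#' @return list with `trace` (a `valid` logical column added) and
#'   `removed` (logical mask of removed samples).
#' @export
removeBlinks <- function(trace, k = 1) {
  if (!nrow(trace)) stop("empty gaze trace")
  dev <- abs(trace$pupil - mean(trace$pupil))
  removed <- dev > k * stats::sd(trace$pupil)
  if (all(removed)) stop("all samples removed by blink filter")
  trace$valid <- !removed
  list(trace = trace, removed = removed)
}

## boxcar-smoothed central-difference velocity (per-sample, units/s)
gazeVelocity <- function(z, fs, smoothWindow_s = 0.005) {
  n <- length(z)
  v <- c(NA, (z[-(1:2)] - z[seq_len(n - 2)]) * fs / 2, NA)
  w <- max(1L, round(smoothWindow_s * fs))
  if (w > 1) {
    kern <- rep(1 / w, w)
    v <- as.numeric(stats::filter(v, kern, sides = 2))
  }
  v
}

#' Velocity-based saccade detection
#'
#' Computes 2-D gaze velocity by boxcar-smoothed central differences,
#' thresholds the speed at `velThresholdK` times its standard deviation
#' over valid samples, and labels contiguous supra-threshold runs of at
#' least `minDuration_s` as saccades. Saccade direction is the planar
#' angle of the net displacement. Events without a pre-onset window of
#' `cleanWindow_s` free of saccades and blinks are kept but flagged
#' invalid. The smoothing window is kept below the duration criterion
#' so that sub-threshold excursions are not smeared past it.
#'
#' @param trace gaze trace; if it carries no `valid` column,
#'   [removeBlinks()] is applied first.
#' @param velThresholdK speed threshold in SD multiples (default 6).
#' @param minDuration_s minimum saccade duration, s (default 0.012).
#' @param cleanWindow_s required pre-saccadic clean window, s
#'   (default 0.2).
#' @param smoothWindow_s velocity smoothing boxcar, s (default 0.005).
#' @return data.frame of saccade events: onset (s), duration (s),
#'   direction (degrees), amplitude (screen units), peakSpeed, valid.
#' @export
detectSaccades <- function(trace, velThresholdK = 6,
                           minDuration_s = 0.012, cleanWindow_s = 0.2,
                           smoothWindow_s = 0.005) {
  fs <- attr(trace, "fs")
  if (is.null(fs)) stop("gaze trace lacks an 'fs' attribute")
  if (nrow(trace) < cleanWindow_s * fs)
    stop("trace shorter than the clean window")
  if (is.null(trace$valid)) trace <- removeBlinks(trace)$trace
  vx <- gazeVelocity(trace$x, fs, smoothWindow_s)
  vy <- gazeVelocity(trace$y, fs, smoothWindow_s)
  speed <- sqrt(vx^2 + vy^2)
  use <- trace$valid & is.finite(speed)
  thr <- velThresholdK * stats::sd(speed[use])
  above <- use & speed > thr

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= round(minDuration_s * fs))
  empty <- data.frame(onset = numeric(), duration = numeric(),
                      direction = numeric(), amplitude = numeric(),
                      peakSpeed = numeric(), valid = logical())
  if (!length(keep)) return(empty)

  events <- do.call(rbind, lapply(keep, function(i) {
    a <- starts[i]; b <- ends[i]
    dx <- trace$x[b] - trace$x[a]
    dy <- trace$y[b] - trace$y[a]
    data.frame(onset = trace$t[a], duration = (b - a + 1) / fs,
               direction = wrapDegrees(atan2(dy, dx) * 180 / pi),
               amplitude = sqrt(dx^2 + dy^2),
               peakSpeed = max(speed[a:b], na.rm = TRUE))
  }))

  ## pre-saccadic clean window: no blink sample and no other saccade
  dirty <- !trace$valid
  for (i in keep) dirty[starts[i]:ends[i]] <- TRUE
  events$valid <- vapply(seq_len(nrow(events)), function(j) {
    onsetIdx <- round((events$onset[j] - trace$t[1]) * fs) + 1L
    w0 <- onsetIdx - round(cleanWindow_s * fs)
    if (w0 < 1) return(FALSE)
    !any(dirty[w0:(onsetIdx - 1L)])
  }, logical(1))
  events
}

#' Convert saccades to grid-analysis events
#'
#' Builds translation-like event rows from detected saccades whose
#' onsets fall within translation periods of the task, carrying the
#' saccade direction as the event direction; the result feeds
#' [runCvGridAnalysis()] unchanged, giving the saccade-direction
#' control analysis.
#'
#' @param saccades data.frame from [detectSaccades()].
#' @param events task event table.
#' @param conditions host conditions (default both translation
#'   conditions).
#' @param validOnly use only saccades with a clean pre-onset window
#'   (default TRUE).
#' @return event table of saccade events (same schema as the input
#'   table).
#' @export
saccadesToEvents <- function(saccades, events,
                             conditions = translationConditions(),
                             validOnly = TRUE) {
  host <- events[events$condition %in% conditions, , drop = FALSE]
  if (validOnly && nrow(saccades))
    saccades <- saccades[saccades$valid, , drop = FALSE]
  out <- emptyEventTable()
  for (i in seq_len(nrow(saccades))) {
    hit <- which(host$onset <= saccades$onset[i] &
                   saccades$onset[i] < host$onset + host$duration)
    if (!length(hit)) next
    h <- host[hit[1], ]
    out <- rbind(out, eventRow(saccades$onset[i], saccades$duration[i],
                               h$condition,
                               direction = saccades$direction[i],
                               trial = h$trial, segment = h$segment,
                               run = h$run))
  }
  rownames(out) <- NULL
  out
}

## even-odd rule point-in-polygon; polygon is a 2-column vertex matrix
pointInPolygon <- function(px, py, poly) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Gaze coverage of areas of interest
#'
#' Fraction of valid gaze samples falling inside the active area of
#' interest (AOI) polygon during each AOI's time window, aggregated to a
#' single percentage over all windows.
#'
#' @param trace gaze trace (a `valid` column is honoured if present).
#' @param aois list of AOIs, each a list with `window` (c(t0, t1),
#'   seconds) and `polygon` (vertex matrix with columns x, y).
#' @return list with `pctInside` (overall %) and `perAoi` (per-window
#'   percentages).
#' @export
aoiCoverage <- function(trace, aois) {
  if (!length(aois)) stop("no AOI windows supplied")
  valid <- if (is.null(trace$valid)) rep(TRUE, nrow(trace)) else
    trace$valid
  inside <- 0L; total <- 0L
  per <- numeric(length(aois))
  for (i in seq_along(aois)) {
    a <- aois[[i]]
    sel <- valid & trace$t >= a$window[1] & trace$t < a$window[2]
    hits <- pointInPolygon(trace$x[sel], trace$y[sel],
                           as.matrix(a$polygon))
    per[i] <- if (length(hits)) 100 * mean(hits) else NA_real_
    inside <- inside + sum(hits); total <- total + length(hits)
  }
  if (total == 0) stop("no valid samples fall inside any AOI window")
  list(pctInside = 100 * inside / total, perAoi = per)
}
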