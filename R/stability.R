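#' Spatial stability of voxel-wise grid orientations
#'
#' Rayleigh statistic for non-uniformity of the voxel-wise orientations
#' within an ROI: orientations (defined modulo `360/n`) are mapped onto
#' the full circle by `theta = n * phi`, and `z = N * Rbar^2` with
#' `Rbar` the mean resultant length. Large z means the voxels agree on a
#' common orientation (high spatial stability); 0 means complete
#' dispersion.
#'
#' @param phi voxel orientations, degrees in `[0, 360/n)`.
#' @param n symmetry fold (default 6).
#' @param pValue also return the standard exponential-approximation
#'   p-value (default FALSE).
#' @return Rayleigh z (or a list with `z`, `n`, `p` if `pValue`).
#' @examples
#' spatialStability(rep(10, 10), 6)        # 10
#' spatialStability(c(0, 0, 30), 6)        # 1/3
#' @export
spatialStability <- function(phi, n = 6, pValue = FALSE) {
  if (length(phi) < 2) stop("need at least 2 voxel orientations")
  theta <- degToRad(n * phi)
  N <- length(theta)
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  z <- N * rbar^2
  if (!pValue) return(z)
  p <- exp(sqrt(1 + 4 * N + 4 * (N^2 - (N * rbar)^2)) - (1 + 2 * N))
  list(z = z, n = N, p = p)
}

#' Temporal stability of voxel-wise grid orientations
#'
#' Percentage of voxels whose orientation changes by no more than the
#' tolerance between two data halves, with the change measured in the
#' n-fold fundamental domain: `d = min(|dphi|, 360/n - |dphi|)`.
#'
#' @param phiFirst,phiSecond paired voxel orientations, degrees.
#' @param n symmetry fold (default 6).
#' @param tolerance stability criterion, degrees (default 15).
#' @return percentage of stable voxels in `[0, 100]`.
#' @examples
#' temporalStability(c(10, 0, 20), c(10, 50, 40), 6)  # 2 of 3 stable
#' @export
temporalStability <- function(phiFirst, phiSecond, n = 6,
                              tolerance = 15) {
  if (length(phiFirst) != length(phiSecond))
    stop("paired orientation vectors differ in length")
  d <- fundamentalDifference(phiFirst, phiSecond, n)
  100 * mean(d <= tolerance)
}

#' Split-half fold definition
#'
#' Partition of a run into a first and second half by trial order, for
#' the representational-stability analysis.
#'
#' @param events event table (or an integer trial count).
#' @return a [cvScheme()] of two folds.
#' @export
splitHalfFolds <- function(events) {
  nTrials <- if (is.numeric(events)) events else
    length(unique(events$trial))
  if (nTrials < 2) stop("need at least 2 trials to split")
  if (nTrials %% 2 == 1)
    warning("odd number of trials; halves differ in size")
  cvScheme("half", nTrials)
}

## voxel-wise quadrature orientations estimated on a subset of trials
voxelOrientations <- function(events, data, trials, symmetry = 6,
                              condition = "observation",
                              method = "ols", hpCutoff_s = 128) {
  condName <- conditionEventName(condition)
  condRows <- events[events$condition == condName, , drop = FALSE]
  estRows <- condRows[condRows$trial %in% trials, , drop = FALSE]
  testTrials <- setdiff(unique(condRows$trial), trials)
  quad <- makeQuadratureModulators(estRows$direction, symmetry)
  ev <- foldEvents(events, condName, testTrials,
                   list(modSin = quad[, "sin"], modCos = quad[, "cos"]))
  X <- buildDesign(ev, repetitionTime(data), nVolumes(data),
                   modulators = c("modSin", "modCos"),
                   hpCutoff_s = hpCutoff_s)
  fit <- fitGlm(X, data, method = method)
  estimateOrientation(fit$betas["modSin", ], fit$betas["modCos", ],
                      symmetry)$voxelPhi
}

#' Representational stability of grid-like codes
#'
#' Partitions a run into halves, estimates voxel-wise grid orientations
#' per half with the quadrature GLM, and summarizes spatial stability
#' (Rayleigh z of the voxel orientations, per half) and temporal
#' stability (% voxels whose orientation agrees across halves within
#' the tolerance).
#'
#' @param events event table of one run.
#' @param data an [ROITimeSeries-class].
#' @param symmetry fold n (default 6).
#' @param condition `"observation"` or `"navigation"`.
#' @param tolerance temporal-stability criterion, degrees (default 15).
#' @param method,hpCutoff_s passed to the GLM.
#' @return An object of class `StabilityResult`: list with `zFirst`,
#'   `zSecond`, `rayleighZ` (mean of halves), `rayleighN` (voxels),
#'   `pctStable`, `tolerance`, `split`, `voxelPhi` (voxels x 2).
#' @export
stabilityAnalysis <- function(events, data, symmetry = 6,
                              condition = "observation", tolerance = 15,
                              method = "ols", hpCutoff_s = 128) {
  condName <- conditionEventName(condition)
  trials <- sort(unique(events$trial[events$condition == condName]))
  halves <- splitHalfFolds(length(trials))
  phi1 <- voxelOrientations(events, data, trials[halves[[1]]], symmetry,
                            condition, method, hpCutoff_s)
  phi2 <- voxelOrientations(events, data, trials[halves[[2]]], symmetry,
                            condition, method, hpCutoff_s)
  z1 <- spatialStability(phi1, symmetry)
  z2 <- spatialStability(phi2, symmetry)
  structure(list(zFirst = z1, zSecond = z2, rayleighZ = mean(c(z1, z2)),
                 rayleighN = length(phi1),
                 pctStable = temporalStability(phi1, phi2, symmetry,
                                               tolerance),
                 tolerance = tolerance, split = "half",
                 voxelPhi = cbind(first = phi1, second = phi2)),
            class = "StabilityResult")
}

#' @export
print.StabilityResult <- function(x, ...) {
  cat(sprintf("StabilityResult (%s split, %d voxels)\n", x$split,
              x$rayleighN))
  cat(sprintf("  Rayleigh z: %.3f (halves %.3f / %.3f)\n", x$rayleighZ,
              x$zFirst, x$zSecond))
  cat(sprintf("  temporally stable voxels (<= %g deg): %.1f%%\n",
              x$tolerance, x$pctStable))
  invisible(x)
}
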