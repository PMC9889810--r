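#' Quadrature direction modulators
#'
#' The sin/cos regressor pair whose betas determine the grid
#' orientation: `sin(n * alpha)` and `cos(n * alpha)`.
#'
#' @param alpha direction(s), degrees.
#' @param n symmetry fold (default 6).
#' @return matrix with columns `sin` and `cos`.
#' @examples
#' makeQuadratureModulators(15, 6)   # (1, 0)
#' @export
makeQuadratureModulators <- function(alpha, n = 6) {
  cbind(sin = sinpi(n * alpha / 180), cos = cospi(n * alpha / 180))
}

#' Grid orientation from quadrature betas
#'
#' ROI-mean orientation `phi = atan2(mean(beta_sin), mean(beta_cos)) / n`
#' mapped into the fundamental domain `[0, 360/n)`, plus the identically
#' computed voxel-wise orientations.
#'
#' @param betaSin,betaCos per-voxel quadrature betas.
#' @param n symmetry fold (default 6).
#' @return list with `phi` (ROI mean, degrees) and `voxelPhi`.
#' @examples
#' estimateOrientation(1, 0, 6)$phi   # 15
#' @export
estimateOrientation <- function(betaSin, betaCos, n = 6) {
  ms <- mean(betaSin); mc <- mean(betaCos)
  if (ms == 0 && mc == 0)
    stop("undefined orientation: both mean quadrature betas are zero")
  phi <- wrapFundamental(atan2(ms, mc) * 180 / pi / n, n)
  voxelPhi <- wrapFundamental(atan2(betaSin, betaCos) * 180 / pi / n, n)
  list(phi = phi, voxelPhi = voxelPhi)
}

#' Alignment modulator
#'
#' `cos(n * (alpha - phi))`: +1 when the movement direction is aligned
#' with a grid axis, -1 when maximally misaligned.
#'
#' @param alpha direction(s), degrees.
#' @param phi grid orientation, degrees.
#' @param n symmetry fold (default 6).
#' @return numeric vector.
#' @export
alignmentModulator <- function(alpha, phi, n = 6) {
  cospi(n * (alpha - phi) / 180)
}

#' Cross-validation scheme over trials
#'
#' @param kind `"loto"` (leave one trial out), `"parts"` (k consecutive
#'   parts), or `"half"` (first/second half).
#' @param nTrials number of trials in the run (default 12).
#' @param k number of parts for `kind = "parts"`.
#' @return list of folds, each a vector of held-out trial indices.
#' @export
cvScheme <- function(kind = c("loto", "parts", "half"), nTrials = 12,
                     k = 4) {
  kind <- match.arg(kind)
  trials <- seq_len(nTrials)
  folds <- switch(kind,
    loto = as.list(trials),
    parts = split(trials, cut(trials, k, labels = FALSE)),
    half = split(trials, rep(1:2, each = ceiling(nTrials / 2),
                             length.out = nTrials)))
  unname(folds)
}

conditionEventName <- function(condition) {
  switch(match.arg(condition, c("observation", "navigation")),
         observation = "obs_translation",
         navigation = "nav_translation")
}

## assemble GLM1/GLM2 events for one fold: the condition's translation
## rows split into estimation/test groups with modulator columns
foldEvents <- function(events, condName, testTrials, modValuesEst,
                       modValuesTest = NULL) {
  ev <- events
  isCond <- ev$condition %in% condName
  isTest <- isCond & ev$trial %in% testTrials
  isEst <- isCond & !isTest
  ev$condition[isTest] <- paste0(condName, "_test")
  ev$condition[isEst] <- paste0(condName, "_est")
  for (m in names(modValuesEst)) {
    ev[[m]] <- NA_real_
    ev[[m]][isEst] <- modValuesEst[[m]]
  }
  for (m in names(modValuesTest)) {
    ev[[m]] <- NA_real_
    ev[[m]][isTest] <- modValuesTest[[m]]
  }
  ev
}

#' Cross-validated grid orientation estimation and magnitude testing
#'
#' The core analysis. Per cross-validation fold, grid orientations are
#' estimated on the held-in trials with a quadrature-modulator GLM
#' (translation events modulated by `sin(n*alpha)` and `cos(n*alpha)`;
#' orientation from the four-quadrant arctangent of the voxel-mean
#' betas). The orientation fit is then tested on the held-out trial with
#' an alignment-modulator GLM: translation events modulated by
#' `cos(n*(alpha - phi_fold))`, the held-out events carrying their own
#' modulator regressor whose beta is the fold's grid magnitude (held-in
#' events contribute a separate modulator regressor as a covariate by
#' default; set `modulatorScope = "test_only"` to drop it). Per-segment
#' magnitudes are assigned from the fold beta and the segment's
#' alignment (see `segmentMagnitude`), and the subject-level magnitude
#' is the mean over folds, then voxels, of the held-out betas.
#'
#' @param events event table of one run.
#' @param data an [ROITimeSeries-class] aligned to `events`.
#' @param symmetry tested fold n (default 6).
#' @param scheme a [cvScheme()] (default leave-one-trial-out over the
#'   trials present).
#' @param condition `"observation"` or `"navigation"`.
#' @param voxelwise estimate and test orientations per voxel instead of
#'   using the ROI-mean orientation (default FALSE).
#' @param modulatorScope `"split"` (default) or `"test_only"`, see above.
#' @param segmentMagnitude `"cosine_scaled"` (default,
#'   `m_s = beta_fold * cos(n*(alpha_s - phi_fold))`) or `"fold_beta"`
#'   (`m_s = beta_fold`).
#' @param method GLM estimator passed to [fitGlm()].
#' @param hpCutoff_s high-pass cutoff, s (default 128).
#' @return A [GridCVResult-class].
#' @examples
#' run <- generateRunPaths(seed = 3)
#' ev <- scheduleEvents(run, seed = 3, includeNavigation = FALSE)
#' ts <- simulateRoiBold(ev, groundTruth(phi = 23), nVoxels = 4, seed = 3)
#' res <- runCvGridAnalysis(ev, ts, symmetry = 6,
#'                          condition = "observation")
#' subjectMagnitude(res)
#' @export
runCvGridAnalysis <- function(events, data, symmetry = 6,
                              scheme = NULL,
                              condition = c("observation", "navigation"),
                              voxelwise = FALSE,
                              modulatorScope = c("split", "test_only"),
                              segmentMagnitude = c("cosine_scaled",
                                                   "fold_beta"),
                              method = "ols", hpCutoff_s = 128) {
  condition <- match.arg(condition)
  modulatorScope <- match.arg(modulatorScope)
  segmentMagnitude <- match.arg(segmentMagnitude)
  condName <- conditionEventName(condition)
  condRows <- events[events$condition == condName, , drop = FALSE]
  if (!nrow(condRows)) stop("condition '", condition,
                            "' not present in events")
  trials <- sort(unique(condRows$trial))
  if (length(trials) < 2) stop("need at least 2 trials for CV")
  if (is.null(scheme)) scheme <- cvScheme("loto", length(trials))
  tr <- repetitionTime(data)
  nVol <- nVolumes(data)
  V <- nVoxels(data)
  n <- symmetry

  nFolds <- length(scheme)
  undefinedFolds <- degenerateFolds <- integer(0)
  foldPhi <- rep(NA_real_, nFolds)
  voxelPhi <- matrix(NA_real_, V, nFolds)
  betas <- matrix(NA_real_, V, nFolds)
  segMag <- vector("list", nFolds)

  for (f in seq_len(nFolds)) {
    testTrials <- trials[scheme[[f]]]
    if (length(testTrials) >= length(trials))
      stop("fold ", f, " holds out every trial")
    estRows <- condRows[!condRows$trial %in% testTrials, , drop = FALSE]
    testRows <- condRows[condRows$trial %in% testTrials, , drop = FALSE]

    ## GLM1: quadrature estimation on held-in trials
    quad <- makeQuadratureModulators(estRows$direction, n)
    ev1 <- foldEvents(events, condName, testTrials,
                      list(modSin = quad[, "sin"],
                           modCos = quad[, "cos"]))
    X1 <- buildDesign(ev1, tr, nVol, modulators = c("modSin", "modCos"),
                      hpCutoff_s = hpCutoff_s)
    fit1 <- fitGlm(X1, data, method = method)
    bSin <- fit1$betas["modSin", ]
    bCos <- fit1$betas["modCos", ]
    orient <- tryCatch(estimateOrientation(bSin, bCos, n),
                       error = function(e) NULL)
    if (is.null(orient)) {
      undefinedFolds <- c(undefinedFolds, f)
      next
    }
    foldPhi[f] <- orient$phi
    voxelPhi[, f] <- orient$voxelPhi

    ## GLM2: alignment testing on the held-out trial
    if (voxelwise) {
      for (v in seq_len(V)) {
        phiV <- orient$voxelPhi[v]
        betas[v, f] <- alignmentBeta(
          events, condName, testTrials, estRows, testRows, phiV, n, tr,
          nVol, data@data[, v, drop = FALSE], modulatorScope, method,
          hpCutoff_s)
      }
      phiUsed <- orient$voxelPhi
    } else {
      betas[, f] <- alignmentBeta(
        events, condName, testTrials, estRows, testRows, orient$phi, n,
        tr, nVol, data, modulatorScope, method, hpCutoff_s)
      phiUsed <- orient$phi
    }

    if (!any(is.finite(betas[, f]))) {
      degenerateFolds <- c(degenerateFolds, f)
      next
    }
    foldBeta <- mean(betas[, f], na.rm = TRUE)
    mS <- switch(segmentMagnitude,
                 cosine_scaled = foldBeta *
                   alignmentModulator(testRows$direction,
                                      if (voxelwise) mean(phiUsed) else
                                        phiUsed, n),
                 fold_beta = rep(foldBeta, nrow(testRows)))
    segMag[[f]] <- data.frame(fold = f, trial = testRows$trial,
                              segment = testRows$segment,
                              direction = testRows$direction,
                              magnitude = mS)
  }

  if (length(undefinedFolds))
    warning("fold(s) ", paste(undefinedFolds, collapse = ", "),
            ": undefined orientation (zero mean quadrature betas), ",
            "excluded from the fold average")
  if (length(degenerateFolds))
    warning("fold(s) ", paste(degenerateFolds, collapse = ", "),
            ": held-out directions congruent modulo ", 360 / n,
            " degrees, magnitude undefined, excluded from the fold ",
            "average")
  okFolds <- which(is.finite(foldPhi) &
                     apply(betas, 2, function(b) any(is.finite(b))))
  if (!length(okFolds))
    stop("no fold produced a defined orientation and magnitude")
  subject <- mean(betas[, okFolds], na.rm = TRUE)
  methods::new("GridCVResult", symmetry = as.numeric(symmetry),
               condition = condition, foldPhi = foldPhi,
               voxelPhi = voxelPhi, foldBetas = betas,
               segmentMagnitudes = do.call(rbind, segMag),
               subjectMagnitude = subject,
               options = list(voxelwise = voxelwise,
                              modulatorScope = modulatorScope,
                              segmentMagnitude = segmentMagnitude,
                              method = method, hpCutoff_s = hpCutoff_s,
                              scheme = scheme))
}

## held-out alignment-modulator beta(s) of one fold (GLM2); NA when the
## held-out alignment values are all equal (directions congruent modulo
## 360/n), which leaves the centered modulator with no variance
alignmentBeta <- function(events, condName, testTrials, estRows,
                          testRows, phi, n, tr, nVol, data,
                          modulatorScope, method, hpCutoff_s) {
  testVals <- alignmentModulator(testRows$direction, phi, n)
  if (diff(range(testVals)) < 1e-9) {
    nv <- if (methods::is(data, "ROITimeSeries")) nVoxels(data) else
      ncol(as.matrix(data))
    return(rep(NA_real_, nv))
  }
  modEst <- if (modulatorScope == "split")
    list(modAlignEst = alignmentModulator(estRows$direction, phi, n))
  else list()
  ev2 <- foldEvents(events, condName, testTrials, modEst,
                    list(modAlignTest = testVals))
  X2 <- buildDesign(ev2, tr, nVol,
                    modulators = c(names(modEst), "modAlignTest"),
                    hpCutoff_s = hpCutoff_s)
  fit2 <- fitGlm(X2, data, method = method)
  fit2$betas["modAlignTest", ]
}

#' Per-segment grid magnitudes
#'
#' Assigns a magnitude to each held-out path segment from the fold's
#' test beta: either scaled by the segment's alignment with the fold
#' orientation (default) or the fold beta itself.
#'
#' @param foldBeta the fold's held-out alignment beta.
#' @param phi the fold's estimated orientation, degrees.
#' @param directions held-out segment directions, degrees.
#' @param n symmetry fold (default 6).
#' @param mode `"cosine_scaled"` or `"fold_beta"`.
#' @return numeric vector of per-segment magnitudes.
#' @export
segmentwiseMagnitudes <- function(foldBeta, phi, directions, n = 6,
                                  mode = c("cosine_scaled",
                                           "fold_beta")) {
  mode <- match.arg(mode)
  switch(mode,
         cosine_scaled = foldBeta * alignmentModulator(directions, phi,
                                                       n),
         fold_beta = rep(foldBeta, length(directions)))
}

#' Design with translation events modulated by grid magnitudes
#'
#' Builds the follow-up design in which each translation event is
#' parametrically modulated by its segment-specific grid magnitude
#' (mean-centered), e.g. to localize activity time-locked to grid-code
#' strength.
#'
#' @param events event table.
#' @param magnitudes one magnitude per translation event of `condition`,
#'   in event order.
#' @param tr repetition time, s.
#' @param nVolumes number of volumes.
#' @param condition `"observation"` or `"navigation"`.
#' @param ... passed to [buildDesign()].
#' @return A `DesignMatrix` with a `gridMagnitude` regressor.
#' @export
buildMagnitudeModulatedDesign <- function(events, magnitudes, tr,
                                          nVolumes,
                                          condition = "observation",
                                          ...) {
  condName <- conditionEventName(condition)
  sel <- events$condition == condName
  if (sum(sel) != length(magnitudes))
    stop("need one magnitude per '", condName, "' event (",
         sum(sel), " events, ", length(magnitudes), " magnitudes)")
  events$gridMagnitude <- NA_real_
  events$gridMagnitude[sel] <- magnitudes
  buildDesign(events, tr, nVolumes, modulators = "gridMagnitude", ...)
}

#' Median-absolute-deviation outlier filter
#'
#' Keeps values within `k` (unscaled) median absolute deviations of the
#' median.
#'
#' @param values numeric vector.
#' @param k exclusion multiple (default 3).
#' @return logical keep-mask.
#' @examples
#' madOutlierFilter(c(1:9, 100))
#' @export
madOutlierFilter <- function(values, k = 3) {
  if (!length(values)) stop("empty input")
  med <- stats::median(values)
  madU <- stats::median(abs(values - med))
  abs(values - med) <= k * madU
}

#' Test a fixed grid orientation on other data
#'
#' Alignment-modulator magnitude on a condition/run using an externally
#' supplied orientation (no re-estimation), e.g. testing observation
#' orientations on navigation periods.
#'
#' @param phi source orientation, degrees.
#' @param events,data target run events and time series.
#' @param symmetry fold n (default 6).
#' @param condition target condition.
#' @param method,hpCutoff_s passed to the GLM.
#' @return list with `magnitude` (voxel mean) and `voxelBetas`.
#' @export
orientationTransferTest <- function(phi, events, data, symmetry = 6,
                                    condition = "observation",
                                    method = "ols", hpCutoff_s = 128) {
  condName <- conditionEventName(condition)
  sel <- events$condition == condName
  if (!any(sel)) stop("condition not present in events")
  events$modAlign <- NA_real_
  events$modAlign[sel] <- alignmentModulator(events$direction[sel], phi,
                                             symmetry)
  X <- buildDesign(events, repetitionTime(data), nVolumes(data),
                   modulators = "modAlign", hpCutoff_s = hpCutoff_s)
  fit <- fitGlm(X, data, method = method)
  b <- fit$betas["modAlign", ]
  list(magnitude = mean(b), voxelBetas = b)
}

#' One-sample group test of subject grid magnitudes
#'
#' MAD-based outlier exclusion followed by a one-sample location test
#' against zero with the stated tail, Cohen's d, a 95% confidence
#' interval, and a Bonferroni-adjusted significance flag.
#'
#' @param magnitudes subject-level grid magnitudes.
#' @param tail `"greater"` (default), `"less"` or `"two.sided"`.
#' @param alpha nominal level (default 0.05).
#' @param bonferroniM number of comparisons corrected for (default 1).
#' @param madK MAD exclusion multiple (default 3); NA disables
#'   filtering.
#' @return list with `n`, `mean`, `sem`, `t`, `dof`, `p`, `d`, `ci`,
#'   `alphaAdjusted`, `significant`, `kept`.
#' @export
groupSummary <- function(magnitudes, tail = c("greater", "less",
                                              "two.sided"),
                         alpha = 0.05, bonferroniM = 1, madK = 3) {
  tail <- match.arg(tail)
  kept <- if (is.finite(madK)) madOutlierFilter(magnitudes, madK) else
    rep(TRUE, length(magnitudes))
  x <- magnitudes[kept]
  if (length(x) < 2) stop("fewer than 2 values after outlier filtering")
  alphaAdj <- alpha / bonferroniM
  if (stats::sd(x) == 0) {
    m <- mean(x)
    tStat <- if (m == 0) 0 else Inf * sign(m)
    p <- if (m == 0) {
      if (tail == "two.sided") 1 else 0.5
    } else if (tail == "two.sided") 0 else
      if ((tail == "greater") == (m > 0)) 0 else 1
    return(list(n = length(x), mean = m, sem = 0, t = tStat,
                dof = length(x) - 1, p = p,
                d = if (m == 0) 0 else Inf * sign(m),
                ci = c(m, m), alphaAdjusted = alphaAdj,
                significant = p < alphaAdj, kept = kept))
  }
  ht <- stats::t.test(x, mu = 0, alternative = tail)
  ci <- stats::t.test(x, mu = 0)$conf.int
  list(n = length(x), mean = mean(x),
       sem = stats::sd(x) / sqrt(length(x)),
       t = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value, d = mean(x) / stats::sd(x),
       ci = as.numeric(ci), alphaAdjusted = alphaAdj,
       significant = ht$p.value < alphaAdj, kept = kept)
}
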