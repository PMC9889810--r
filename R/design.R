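#' Canonical haemodynamic response kernel
#'
#' Double-gamma haemodynamic response function: the difference of two
#' gamma densities (response peaking near 5 s, undershoot near 15 s,
#' scaled by the undershoot ratio), sampled on a microtime grid and
#' peak-normalized to a maximum of 1.
#'
#' @param dt microtime resolution, s (default 0.1).
#' @param responseDelay,undershootDelay gamma delays, s (defaults 6, 16).
#' @param responseDispersion,undershootDispersion gamma dispersions
#'   (defaults 1, 1).
#' @param undershootRatio response/undershoot amplitude ratio (default 6).
#' @param length_s kernel support, s (default 32).
#' @return numeric kernel sampled at `dt`, first sample 0, max 1.
#' @examples
#' h <- canonicalHrf()
#' (which.max(h) - 1) * 0.1   # peak latency, s
#' @export
canonicalHrf <- function(dt = 0.1, responseDelay = 6,
                         undershootDelay = 16, responseDispersion = 1,
                         undershootDispersion = 1, undershootRatio = 6,
                         length_s = 32) {
  stopifnot(dt > 0, responseDelay > 0, undershootDelay > 0,
            responseDispersion > 0, undershootDispersion > 0,
            undershootRatio > 0, length_s > 0)
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = responseDelay / responseDispersion,
                     scale = responseDispersion) -
    stats::dgamma(t, shape = undershootDelay / undershootDispersion,
                  scale = undershootDispersion) / undershootRatio
  h / max(h)
}

#' Discrete-cosine high-pass basis
#'
#' The cosine regressors (constant term excluded) spanning fluctuations
#' slower than the cutoff period, as used to high-pass filter fMRI
#' designs.
#'
#' @param nVolumes number of volumes.
#' @param tr repetition time, s.
#' @param cutoff_s cutoff period, s (default 128).
#' @return matrix `nVolumes` x K (possibly 0 columns).
#' @export
dctBasis <- function(nVolumes, tr, cutoff_s = 128) {
  K <- floor(2 * nVolumes * tr / cutoff_s)
  K <- max(0L, min(K, nVolumes - 1L))
  if (K == 0L)
    return(matrix(numeric(0), nVolumes, 0))
  i <- seq_len(nVolumes) - 1L
  basis <- vapply(seq_len(K), function(k)
    sqrt(2 / nVolumes) * cos(pi * (2 * i + 1) * k / (2 * nVolumes)),
    numeric(nVolumes))
  colnames(basis) <- paste0("dct", seq_len(K))
  basis
}

## microtime boxcar of a set of events, optionally scaled per event
microtimeBoxcar <- function(onsets, durations, weights, nSamples, dt) {
  x <- numeric(nSamples)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- max(a, ceiling((onsets[i] + durations[i]) / dt))
    if (b > nSamples)
      stop("event extends past the end of the scan")
    x[a:b] <- x[a:b] + weights[i]
  }
  x
}

convolveResample <- function(x, kernel, volumeIdx, dt) {
  n <- length(x)
  conv <- stats::convolve(x, rev(kernel), type = "open")[seq_len(n)] * dt
  conv[volumeIdx]
}

#' Build a first-level fMRI design matrix
#'
#' One convolved boxcar regressor per modeled condition, plus, for each
#' requested parametric modulator, a regressor whose microtime boxcar is
#' scaled per event by the modulator value (mean-centered across the
#' events that carry it) before convolution. A discrete-cosine high-pass
#' basis and a constant term are appended; nuisance columns are appended
#' verbatim. Events are resolved at microtime resolution, convolved with
#' the canonical haemodynamic kernel and resampled at volume acquisition
#' midpoints. Rotation, standing and delay periods are left unmodeled
#' (implicit baseline) unless listed in `conditions`.
#'
#' @param events event table (see [scheduleEvents()]); modulator values
#'   are taken from columns of `events` named in `modulators`, applied to
#'   the rows where they are non-NA.
#' @param tr repetition time, s.
#' @param nVolumes number of volumes.
#' @param modulators character vector of modulator column names.
#' @param conditions conditions to model; default: all except rotation,
#'   standing and delay.
#' @param hrf kernel from [canonicalHrf()] evaluated at `microtime`.
#' @param hpCutoff_s high-pass cutoff, s (default 128; NA disables).
#' @param nuisance optional numeric matrix of nuisance columns.
#' @param microtime microtime resolution, s (default 0.1).
#' @param centerModulators mean-center modulator values before scaling
#'   (default TRUE).
#' @return A `DesignMatrix`: list with `matrix` (`nVolumes` x
#'   regressors), `names`, `frameTimes`, `hpCutoff_s`.
#' @export
buildDesign <- function(events, tr, nVolumes, modulators = character(),
                        conditions = NULL, hrf = NULL, hpCutoff_s = 128,
                        nuisance = NULL, microtime = 0.1,
                        centerModulators = TRUE) {
  validateEventTable(events)
  if (is.null(hrf)) hrf <- canonicalHrf(dt = microtime)
  if (is.null(conditions))
    conditions <- setdiff(unique(events$condition),
                          c("rotation", "standing", "delay"))
  missingMod <- setdiff(modulators, names(events))
  if (length(missingMod))
    stop("unknown modulator column(s): ",
         paste(missingMod, collapse = ", "))
  total <- nVolumes * tr
  if (any(events$onset + events$duration > total))
    stop("event extends past the end of the scan")
  nSamples <- ceiling(total / microtime) + length(hrf)
  volumeIdx <- pmin(nSamples,
                    floor(((seq_len(nVolumes) - 0.5) * tr) / microtime) + 1L)

  cols <- list()
  for (cond in conditions) {
    rows <- events[events$condition == cond, , drop = FALSE]
    if (!nrow(rows)) next
    x <- microtimeBoxcar(rows$onset, rows$duration,
                         rep(1, nrow(rows)), nSamples, microtime)
    cols[[cond]] <- convolveResample(x, hrf, volumeIdx, microtime)
  }
  for (mod in modulators) {
    vals <- events[[mod]]
    sel <- which(!is.na(vals))
    if (!length(sel)) stop("modulator '", mod, "' has no events")
    w <- vals[sel]
    if (centerModulators) w <- w - mean(w)
    x <- microtimeBoxcar(events$onset[sel], events$duration[sel], w,
                         nSamples, microtime)
    cols[[mod]] <- convolveResample(x, hrf, volumeIdx, microtime)
  }
  X <- do.call(cbind, cols)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  if (is.finite(hpCutoff_s)) {
    dct <- dctBasis(nVolumes, tr, hpCutoff_s)
    if (ncol(dct)) X <- cbind(X, dct)
  }
  X <- cbind(X, constant = 1)
  if (anyDuplicated(colnames(X)))
    stop("duplicate regressor names in design")
  structure(list(matrix = X, names = colnames(X),
                 frameTimes = (seq_len(nVolumes) - 0.5) * tr,
                 hpCutoff_s = hpCutoff_s),
            class = "DesignMatrix")
}

#' @export
print.DesignMatrix <- function(x, ...) {
  cat(sprintf("DesignMatrix: %d volumes x %d regressors\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  regressors:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a mass-univariate linear model
#'
#' Per-voxel least squares of an ROI time series on a design matrix,
#' optionally after AR(1) prewhitening with a pooled autocorrelation
#' estimated from the OLS residuals.
#'
#' @param design a `DesignMatrix` from [buildDesign()], or a plain
#'   numeric matrix.
#' @param data an [ROITimeSeries-class] or a volumes x voxels matrix.
#' @param method `"ols"` (default) or `"ar1"`.
#' @return A `FitResult`: list with `betas` (regressors x voxels),
#'   `residualVariance`, `dof`, `method`, `rho` (AR(1) only).
#' @export
fitGlm <- function(design, data, method = c("ols", "ar1")) {
  method <- match.arg(method)
  X <- if (inherits(design, "DesignMatrix")) design$matrix else
    as.matrix(design)
  Y <- if (methods::is(data, "ROITimeSeries")) boldData(data) else
    as.matrix(data)
  if (nrow(X) != nrow(Y))
    stop("design and data row counts differ (",
         nrow(X), " vs ", nrow(Y), ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient (rank ", qrX$rank, " < ",
         ncol(X), " columns)")
  fit <- stats::lm.fit(X, Y)
  betas <- as.matrix(fit$coefficients)
  res <- as.matrix(fit$residuals)
  rho <- NULL
  if (method == "ar1") {
    n <- nrow(res)
    rho <- sum(res[-1, ] * res[-n, ]) / sum(res[-n, ]^2)
    W <- function(M) rbind(M[1, ] * sqrt(1 - rho^2),
                           M[-1, , drop = FALSE] -
                             rho * M[-n, , drop = FALSE])
    Xw <- W(X); Yw <- W(Y)
    fit <- stats::lm.fit(Xw, Yw)
    betas <- as.matrix(fit$coefficients)
    res <- as.matrix(fit$residuals)
  }
  dof <- nrow(res) - qrX$rank
  if (dof <= 0) stop("non-positive residual degrees of freedom")
  structure(list(betas = betas,
                 residualVariance = colSums(res^2) / dof,
                 dof = dof, method = method, rho = rho,
                 names = colnames(X)),
            class = "FitResult")
}
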