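#' ROITimeSeries: a region-of-interest BOLD time-series matrix
#'
#' Container for the voxel time series all model fits operate on: a
#' volumes-by-voxels numeric matrix together with the repetition time (TR,
#' seconds) of the acquisition. Simulated series additionally carry their
#' generating parameters in `metadata` so recovery tests can compare
#' against ground truth.
#'
#' @slot data numeric matrix, volumes x voxels.
#' @slot tr repetition time in seconds.
#' @slot voxelIds character vector of voxel identifiers.
#' @slot metadata list of provenance (seed, ground truth, ...).
#'
#' @export
setClass("ROITimeSeries",
         representation(data = "matrix", tr = "numeric",
                        voxelIds = "character", metadata = "list"),
         prototype(metadata = list()))

setValidity("ROITimeSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@data) || !all(is.finite(object@data)))
    msg <- c(msg, "'data' must be a finite numeric matrix")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    msg <- c(msg, "'tr' must be a single positive number")
  if (length(object@voxelIds) != ncol(object@data))
    msg <- c(msg, "'voxelIds' must match the number of voxels (columns)")
  if (length(msg)) msg else TRUE
})

#' Construct an ROITimeSeries
#'
#' @param data volumes x voxels numeric matrix.
#' @param tr repetition time in seconds (default 2.029).
#' @param voxelIds optional voxel identifiers; defaults to `v1, v2, ...`.
#' @param metadata optional provenance list.
#' @return An [ROITimeSeries-class] object.
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(40), 20, 2), tr = 2.029)
#' nVolumes(ts)
#' @export
ROITimeSeries <- function(data, tr = 2.029, voxelIds = NULL,
                          metadata = list()) {
  data <- as.matrix(data)
  if (is.null(voxelIds)) voxelIds <- paste0("v", seq_len(ncol(data)))
  colnames(data) <- voxelIds
  methods::new("ROITimeSeries", data = data, tr = tr,
               voxelIds = as.character(voxelIds), metadata = metadata)
}

#' @describeIn ROITimeSeries-class the volumes x voxels data matrix
#' @param object,x an `ROITimeSeries`
#' @export
setGeneric("boldData", function(object) standardGeneric("boldData"))

#' @rdname ROITimeSeries-class
#' @export
setMethod("boldData", "ROITimeSeries", function(object) object@data)

#' @describeIn ROITimeSeries-class the repetition time in seconds
#' @export
setGeneric("repetitionTime",
           function(object) standardGeneric("repetitionTime"))

#' @rdname ROITimeSeries-class
#' @export
setMethod("repetitionTime", "ROITimeSeries", function(object) object@tr)

#' @describeIn ROITimeSeries-class number of volumes (rows)
#' @export
setGeneric("nVolumes", function(object) standardGeneric("nVolumes"))

#' @rdname ROITimeSeries-class
#' @export
setMethod("nVolumes", "ROITimeSeries", function(object) nrow(object@data))

#' @describeIn ROITimeSeries-class number of voxels (columns)
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))

#' @rdname ROITimeSeries-class
#' @export
setMethod("nVoxels", "ROITimeSeries", function(object) ncol(object@data))

#' @describeIn ROITimeSeries-class voxel identifiers
#' @export
setGeneric("voxelIds", function(object) standardGeneric("voxelIds"))

#' @rdname ROITimeSeries-class
#' @export
setMethod("voxelIds", "ROITimeSeries", function(object) object@voxelIds)

setMethod("show", "ROITimeSeries", function(object) {
  cat("ROITimeSeries:", nVolumes(object), "volumes x", nVoxels(object),
      "voxels, TR =", object@tr, "s",
      sprintf("(%.1f s total)\n", nVolumes(object) * object@tr))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' GridCVResult: cross-validated grid orientation and magnitude estimates
#'
#' The output of [runCvGridAnalysis()]: per-fold grid orientations
#' (ROI-mean and voxel-wise), per-fold held-out magnitude betas, path
#' segment-wise magnitudes, and the subject-level magnitude obtained by
#' averaging over folds and voxels.
#'
#' @slot symmetry integer fold of the directional periodicity (6 for a
#'   hexadirectional code).
#' @slot condition analysed condition ("observation" or "navigation").
#' @slot foldPhi numeric vector of per-fold ROI-mean orientations, degrees
#'   in `[0, 360/n)`.
#' @slot voxelPhi voxels x folds matrix of voxel-wise orientations.
#' @slot foldBetas voxels x folds matrix of held-out alignment betas.
#' @slot segmentMagnitudes data.frame with one row per held-out path
#'   segment (fold, trial, segment, direction, magnitude).
#' @slot subjectMagnitude the fold- and voxel-averaged magnitude.
#' @slot options list of analysis options used.
#'
#' @export
setClass("GridCVResult",
         representation(symmetry = "numeric", condition = "character",
                        foldPhi = "numeric", voxelPhi = "matrix",
                        foldBetas = "matrix",
                        segmentMagnitudes = "data.frame",
                        subjectMagnitude = "numeric", options = "list"))

setValidity("GridCVResult", function(object) {
  msg <- character()
  if (object@symmetry < 1) msg <- c(msg, "'symmetry' must be >= 1")
  ok <- is.finite(object@foldPhi)
  if (any(object@foldPhi[ok] < 0 |
          object@foldPhi[ok] >= 360 / object@symmetry))
    msg <- c(msg, "fold orientations outside the fundamental domain")
  if (length(msg)) msg else TRUE
})

#' @describeIn GridCVResult-class subject-level grid magnitude (mean over
#'   folds, then voxels)
#' @param object a `GridCVResult`
#' @export
setGeneric("subjectMagnitude",
           function(object) standardGeneric("subjectMagnitude"))

#' @rdname GridCVResult-class
#' @export
setMethod("subjectMagnitude", "GridCVResult",
          function(object) object@subjectMagnitude)

#' @describeIn GridCVResult-class per-fold ROI-mean orientations (degrees)
#' @export
setGeneric("foldOrientations",
           function(object) standardGeneric("foldOrientations"))

#' @rdname GridCVResult-class
#' @export
setMethod("foldOrientations", "GridCVResult", function(object) object@foldPhi)

#' @describeIn GridCVResult-class voxels x folds matrix of held-out betas
#' @export
setGeneric("foldBetas", function(object) standardGeneric("foldBetas"))

#' @rdname GridCVResult-class
#' @export
setMethod("foldBetas", "GridCVResult", function(object) object@foldBetas)

#' @describeIn GridCVResult-class per-segment magnitudes (data.frame)
#' @export
setGeneric("segmentMagnitudes",
           function(object) standardGeneric("segmentMagnitudes"))

#' @rdname GridCVResult-class
#' @export
setMethod("segmentMagnitudes", "GridCVResult",
          function(object) object@segmentMagnitudes)

setMethod("show", "GridCVResult", function(object) {
  cat(sprintf("GridCVResult: %d-fold symmetry, condition '%s'\n",
              object@symmetry, object@condition))
  cat(sprintf("  %d CV folds, %d voxels\n", length(object@foldPhi),
              nrow(object@foldBetas)))
  cat(sprintf("  subject magnitude: %.4f\n", object@subjectMagnitude))
})
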