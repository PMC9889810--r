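#' Read and write event tables
#'
#' Tab-separated event tables with a header row, seconds and period
#' decimals, missing values written as `n/a` (BIDS events dialect).
#' Reading validates the schema (required columns, non-decreasing
#' onsets, directions on translation rows).
#'
#' @param events an event table.
#' @param path file path.
#' @return `readEvents` returns the validated event table;
#'   `writeEvents` returns `path` invisibly.
#' @export
writeEvents <- function(events, path) {
  validateEventTable(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  ev <- utils::read.delim(path, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  validateEventTable(ev)
  ev
}

#' Read and write ROI time series
#'
#' The data matrix is written as a tab-separated table (volumes x
#' voxels, header row of voxel ids) with a YAML sidecar (`<path>.yaml`)
#' declaring the repetition time and any provenance metadata.
#'
#' @param ts an [ROITimeSeries-class].
#' @param path data file path (sidecar is `<path>.yaml`).
#' @param tr optional expected repetition time; a mismatch with the
#'   sidecar is an error.
#' @return `readBold` returns an `ROITimeSeries`; `writeBold` returns
#'   `path` invisibly.
#' @export
writeBold <- function(ts, path) {
  stopifnot(methods::is(ts, "ROITimeSeries"))
  utils::write.table(boldData(ts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- ts@metadata
  meta$truth <- if (!is.null(meta$truth)) unclass(meta$truth)
  meta$noise <- if (!is.null(meta$noise)) unclass(meta$noise)
  side <- c(list(tr = repetitionTime(ts)), meta)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeBold
#' @export
readBold <- function(path, tr = NULL) {
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  if (is.null(side$tr)) stop("BOLD sidecar lacks a 'tr' entry")
  if (!is.null(tr) && abs(tr - side$tr) > 1e-9)
    stop("sidecar tr (", side$tr, ") does not match expected tr (", tr,
         ")")
  dat <- as.matrix(utils::read.delim(path, check.names = FALSE))
  meta <- side[setdiff(names(side), "tr")]
  ROITimeSeries(dat, tr = side$tr, voxelIds = colnames(dat),
                metadata = meta)
}

#' Read and write gaze traces
#'
#' Tab-separated sample table (t, x, y, pupil) with a YAML sidecar
#' declaring the sampling rate.
#'
#' @param trace gaze trace with an `fs` attribute.
#' @param path data file path.
#' @return `readGaze` returns the trace with `fs` restored;
#'   `writeGaze` returns `path` invisibly.
#' @export
writeGaze <- function(trace, path) {
  fs <- attr(trace, "fs")
  if (is.null(fs)) stop("gaze trace lacks an 'fs' attribute")
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(list(fs = fs), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeGaze
#' @export
readGaze <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  if (is.null(side$fs)) stop("gaze sidecar lacks an 'fs' entry")
  trace <- utils::read.delim(path)
  need <- c("t", "x", "y", "pupil")
  miss <- setdiff(need, names(trace))
  if (length(miss))
    stop("gaze table missing columns: ", paste(miss, collapse = ", "))
  attr(trace, "fs") <- side$fs
  trace
}
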