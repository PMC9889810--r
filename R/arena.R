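#' Arena geometry specification
#'
#' Describes the circular virtual-reality arena: a movement area (the disc
#' the demonstrator walks in) surrounded by a larger observation area, a
#' division of the movement area into equal pie-slice sectors used by the
#' path randomization, and the constant walking / rotation speeds.
#'
#' @param movementRadius radius of the movement area, virtual meters
#'   (vm; default 60).
#' @param observationRadius radius of the surrounding observation area,
#'   vm (default 90).
#' @param nSectors number of equal sectors (default 6).
#' @param walkSpeed translation speed, vm/s (default 15).
#' @param rotationSpeed rotation speed, deg/s (default 50).
#' @return An object of class `ArenaSpec` (validated list).
#' @examples
#' arenaSpec()
#' @export
arenaSpec <- function(movementRadius = 60, observationRadius = 90,
                      nSectors = 6, walkSpeed = 15, rotationSpeed = 50) {
  stopifnot(movementRadius > 0, observationRadius > movementRadius,
            nSectors >= 3, walkSpeed > 0, rotationSpeed > 0)
  structure(list(movementRadius = movementRadius,
                 observationRadius = observationRadius,
                 nSectors = nSectors, walkSpeed = walkSpeed,
                 rotationSpeed = rotationSpeed),
            class = "ArenaSpec")
}

#' Direction sampling scheme
#'
#' The allowed segment directions and their grouping into directional
#' bins used to balance direction sampling: `nDirections` directions at
#' `resolution` degrees span the full circle and are grouped into `nBins`
#' bins of equal size. Two groupings are supported: contiguous arcs of
#' `360/nBins` degrees (default) or residue classes modulo `360/nBins`.
#'
#' @param nDirections number of allowed directions (default 36).
#' @param resolution angular resolution in degrees (default 10).
#' @param nBins number of directional bins (default 6).
#' @param binMode `"contiguous"` (60-degree arcs) or `"residue"`
#'   (mod-60 classes).
#' @return An object of class `DirectionScheme`.
#' @examples
#' sch <- directionScheme()
#' binOfDirection(c(5, 65, 359), sch)
#' @export
directionScheme <- function(nDirections = 36, resolution = 10, nBins = 6,
                            binMode = c("contiguous", "residue")) {
  binMode <- match.arg(binMode)
  stopifnot(nDirections * resolution == 360,
            nDirections %% nBins == 0)
  structure(list(nDirections = nDirections, resolution = resolution,
                 nBins = nBins, binMode = binMode,
                 directions = (seq_len(nDirections) - 1) * resolution),
            class = "DirectionScheme")
}

#' Directional bin of a movement direction
#'
#' @param alpha direction(s) in degrees, `[0, 360)`.
#' @param scheme a [directionScheme()].
#' @return Integer bin index (0-based), vectorized over `alpha`.
#' @export
binOfDirection <- function(alpha, scheme = directionScheme()) {
  alpha <- wrapDegrees(alpha)
  arc <- 360 / scheme$nBins
  if (scheme$binMode == "contiguous") {
    floor(alpha / arc)
  } else {
    floor((alpha %% arc) / scheme$resolution) %% scheme$nBins
  }
}

## sector of an angle on the movement-area circumference; half-open
## [60i, 60(i+1)) arcs so a boundary angle belongs to the higher index
sectorOfAngle <- function(angle, nSectors = 6) {
  floor(wrapDegrees(angle) / (360 / nSectors))
}

sectorDistance <- function(i, j, nSectors = 6) {
  d <- abs(i - j) %% nSectors
  pmin(d, nSectors - d)
}

#' Chord geometry between two circumference points
#'
#' Length and planar direction of the straight segment connecting two
#' points on a circle of given radius, the points identified by their
#' polar angles. The direction is the angle of the end-minus-start
#' vector, degrees counterclockwise from the positive x-axis.
#'
#' @param startAngle,endAngle polar angles in degrees, `[0, 360)`.
#' @param radius circle radius (vm).
#' @return list with `length` (vm) and `direction` (degrees).
#' @examples
#' chordGeometry(0, 180, 60)  # a diameter: length 120, direction 180
#' @export
chordGeometry <- function(startAngle, endAngle, radius = 60) {
  sep <- angularSeparation(startAngle, endAngle)
  if (any(sep < 1e-9))
    stop("degenerate segment: start and end angles are identical")
  s <- angleToXY(startAngle, radius)
  e <- angleToXY(endAngle, radius)
  direction <- wrapDegrees(atan2(e[, "y"] - s[, "y"],
                                 e[, "x"] - s[, "x"]) * 180 / pi)
  list(length = chordFromSeparation(sep, radius),
       direction = unname(direction))
}

## end angle of the unique chord leaving `startAngle` in direction `d`;
## returns NA if no such chord exists (direction points out of the disc)
chordEndAngle <- function(startAngle, d, tol = 1e-7) {
  endAngle <- wrapDegrees(2 * (d + 90) - startAngle)
  if (angularSeparation(startAngle, endAngle) < 1e-9) return(NA_real_)
  got <- chordGeometry(startAngle, endAngle, 1)$direction
  if (angularSeparation(got, d) > tol) NA_real_ else endAngle
}

#' Generate the constrained paths of one task run
#'
#' Draws 12 trials of 3 chained path segments each under the balancing
#' constraints of the task design: every segment direction is one of the
#' scheme's allowed directions, the 3 segments of a trial come from 3
#' distinct directional bins, every bin is used exactly 6 times per run,
#' each sector hosts a trial start position exactly twice, and
#' consecutive segment endpoints lie in sectors that are neither
#' identical nor directly adjacent (which enforces segment lengths
#' between 60 and 120 vm at the default geometry). Generation is
#' randomized backtracking: the start-sector schedule is shuffled, bins
#' are drawn per segment from the remaining per-run bin budget, each
#' segment's end point is solved from the required direction via the
#' chord identity, and violations trigger bounded retries with schedule
#' reshuffles.
#'
#' @param arena an [arenaSpec()].
#' @param scheme a [directionScheme()].
#' @param seed optional integer seed; the same seed reproduces the run.
#' @param runIndex stored run index (default 1).
#' @param maxAttempts segment-placement attempts per schedule before the
#'   bin/sector schedules are reshuffled (default 10000).
#' @param maxReshuffles schedule reshuffles before giving up
#'   (default 100).
#' @return A `RunSchedule`: list with `runIndex`, `seed`, and `segments`,
#'   a 36-row data.frame (trial, segment, bin, startAngle, endAngle,
#'   direction, length, startSector, endSector).
#' @examples
#' run <- generateRunPaths(seed = 7)
#' table(run$segments$bin)
#' range(run$segments$length)
#' @export
generateRunPaths <- function(arena = arenaSpec(),
                             scheme = directionScheme(),
                             seed = NULL, runIndex = 1,
                             maxAttempts = 10000, maxReshuffles = 100) {
  if (!is.null(seed)) set.seed(seed)
  nS <- arena$nSectors
  arc <- 360 / nS
  totalAttempts <- 0L

  binDirections <- lapply(seq_len(scheme$nBins) - 1L, function(b)
    scheme$directions[binOfDirection(scheme$directions, scheme) == b])

  ## chain the 3 segments of one trial from a start angle, drawing bins
  ## (distinct within the trial) from the remaining per-run bin budget;
  ## returns a 3 x 5 matrix (startAngle, endAngle, direction, length,
  ## bin) or NULL when no feasible assignment exists from this start
  chainTrial <- function(startAngle, counts) {
    cur <- startAngle
    used <- integer(0)
    out <- matrix(NA_real_, 3, 5)
    for (k in 1:3) {
      avail <- setdiff(which(counts > 0), used)
      if (!length(avail)) return(NULL)
      ## prefer bins with the largest remaining budget to avoid
      ## stranding counts at the end of the run
      ord <- if (length(avail) == 1) avail else
        sample(avail, length(avail), prob = counts[avail]^2)
      found <- FALSE
      for (b in ord) {
        for (d in sample(binDirections[[b]])) {
          endAngle <- (2 * (d + 90) - cur) %% 360
          sep <- abs(endAngle - cur) %% 360
          sep <- min(sep, 360 - sep)
          if (sep < 1e-9) next
          ## direction of the end-minus-start vector must equal d (the
          ## mirrored solution walks out of the disc)
          got <- atan2(sin(endAngle * pi / 180) - sin(cur * pi / 180),
                       cos(endAngle * pi / 180) -
                         cos(cur * pi / 180)) * 180 / pi
          dGot <- abs(((got - d) %% 360))
          if (min(dGot, 360 - dGot) > 1e-7) next
          if (sectorDistance(floor(cur / arc) %% nS,
                             floor(endAngle / arc) %% nS, nS) < 2) next
          out[k, ] <- c(cur, endAngle, d,
                        2 * arena$movementRadius * sin(sep * pi / 360),
                        b - 1L)
          cur <- endAngle
          used <- c(used, b)
          found <- TRUE
          break
        }
        if (found) break
      }
      if (!found) return(NULL)
    }
    out
  }

  for (reshuffle in seq_len(maxReshuffles)) {
    counts <- rep(6L, scheme$nBins)
    startSectors <- sample(rep(seq_len(nS) - 1L, length.out = 12))
    attempts <- 0L
    rows <- vector("list", 12)
    runOk <- TRUE

    for (tr in seq_len(12)) {
      placed <- NULL
      for (try in seq_len(80)) {
        attempts <- attempts + 1L
        totalAttempts <- totalAttempts + 1L
        if (attempts > maxAttempts) break
        startAngle <- startSectors[tr] * arc + stats::runif(1, 0, arc)
        placed <- chainTrial(startAngle, counts)
        if (!is.null(placed)) break
      }
      if (is.null(placed)) { runOk <- FALSE; break }
      counts[placed[, 5] + 1L] <- counts[placed[, 5] + 1L] - 1L
      rows[[tr]] <- placed
    }
    if (runOk) {
      m <- do.call(rbind, rows)
      segments <- data.frame(
        trial = rep(seq_len(12), each = 3),
        segment = rep(1:3, times = 12),
        bin = as.integer(m[, 5]), startAngle = m[, 1],
        endAngle = m[, 2], direction = m[, 3], length = m[, 4],
        startSector = sectorOfAngle(m[, 1], nS),
        endSector = sectorOfAngle(m[, 2], nS))
      out <- structure(list(runIndex = runIndex, seed = seed,
                            segments = segments,
                            arena = arena, scheme = scheme,
                            attempts = totalAttempts,
                            reshuffles = reshuffle),
                       class = "RunSchedule")
      validateRunSchedule(out)
      return(out)
    }
  }
  stop(sprintf(paste0("path generation failed after %d attempts across ",
                      "%d schedule reshuffles; constraints may be ",
                      "unsatisfiable"), totalAttempts, maxReshuffles))
}

validateRunSchedule <- function(run) {
  seg <- run$segments
  stopifnot(nrow(seg) == 36)
  if (!all(table(seg$bin) == 6))
    stop("run invariant violated: bins not used 6 times each")
  byTrial <- split(seg$bin, seg$trial)
  if (!all(vapply(byTrial, function(b) length(unique(b)) == 3L, TRUE)))
    stop("run invariant violated: trial bins not pairwise distinct")
  starts <- seg$startSector[seg$segment == 1]
  if (!all(table(starts) == 2))
    stop("run invariant violated: start sectors not hosted twice")
  invisible(run)
}

#' Correct trial endpoints of a run
#'
#' @param run a `RunSchedule`.
#' @return 12 x 3 matrix of segment end angles (degrees) per trial.
#' @export
trialEndpoints <- function(run) {
  seg <- run$segments
  matrix(seg$endAngle[order(seg$trial, seg$segment)], ncol = 3,
         byrow = TRUE,
         dimnames = list(paste0("trial", 1:12),
                         paste0("segment", 1:3)))
}

#' @export
print.RunSchedule <- function(x, ...) {
  cat(sprintf("RunSchedule (run %d): 12 trials, 36 segments\n", x$runIndex))
  cat(sprintf("  segment lengths %.1f-%.1f vm, %d placement attempts\n",
              min(x$segments$length), max(x$segments$length), x$attempts))
  invisible(x)
}
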