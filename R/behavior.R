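#' Cumulative distance error of a re-traced trial
#'
#' Mean Euclidean (chord) distance, in vm, between the three correct
#' segment endpoints of a trial and the three endpoints the participant
#' actually visited, all identified by their polar angles on the
#' movement-area circumference.
#'
#' @param correct,response numeric vectors of endpoint angles (degrees),
#'   equal length (3 for a standard trial).
#' @param radius movement-area radius, vm (default 60).
#' @return mean chord distance, vm.
#' @examples
#' cumulativeDistanceError(c(0, 120, 240), c(90, 120, 240))
#' @export
cumulativeDistanceError <- function(correct, response, radius = 60) {
  if (length(correct) != length(response))
    stop("correct and response endpoint vectors differ in length")
  mean(chordFromSeparation(angularSeparation(correct, response), radius))
}

#' Permutation-based chance level of a random agent
#'
#' Simulates an agent that, for a trial drawn from the pool of presented
#' paths, picks its three endpoints uniformly at random from the
#' movement-area circumference discretized in `endpointStep`-degree
#' steps. Each iteration yields a trial-mean cumulative distance error;
#' the chance level is the stated percentile of the resulting permutation
#' distribution (5th percentile by default, i.e. the error a random
#' agent undercuts only 5% of the time).
#'
#' @param paths pool of correct paths: a `RunSchedule`, a list of
#'   `RunSchedule`s, or a trials x 3 matrix of endpoint angles (degrees).
#' @param nIter number of permutation iterations (default 5000).
#' @param percentile percentile reported as chance level (default 5).
#' @param endpointStep circumference discretization, degrees (default 1).
#' @param radius movement-area radius, vm (default 60).
#' @param seed optional seed.
#' @return list with `chance` (vm), `percentile`, and `distribution`
#'   (the `nIter` trial-mean errors).
#' @examples
#' runs <- lapply(1:2, function(s) generateRunPaths(seed = s))
#' ch <- randomAgentChance(runs, nIter = 500, seed = 1)
#' ch$chance
#' @export
randomAgentChance <- function(paths, nIter = 5000, percentile = 5,
                              endpointStep = 1, radius = 60,
                              seed = NULL) {
  if (nIter < 1) stop("nIter must be >= 1")
  endpoints <- poolEndpoints(paths)
  if (nrow(endpoints) < 1) stop("empty path pool")
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, 360 - endpointStep, by = endpointStep)
  nSeg <- ncol(endpoints)
  trialIdx <- sample.int(nrow(endpoints), nIter, replace = TRUE)
  draws <- matrix(sample(grid, nIter * nSeg, replace = TRUE), nIter, nSeg)
  errs <- rowMeans(chordFromSeparation(
    angularSeparation(draws, endpoints[trialIdx, , drop = FALSE]),
    radius))
  list(chance = unname(stats::quantile(errs, percentile / 100)),
       percentile = percentile, distribution = errs)
}

poolEndpoints <- function(paths) {
  if (inherits(paths, "RunSchedule")) return(trialEndpoints(paths))
  if (is.list(paths) && all(vapply(paths, inherits, TRUE, "RunSchedule")))
    return(do.call(rbind, lapply(paths, trialEndpoints)))
  as.matrix(paths)
}

#' Normalized re-tracing accuracy of one endpoint
#'
#' Percentile-rank accuracy of a response endpoint relative to the
#' random-agent error distribution for the same correct endpoint: the
#' fraction of random-agent errors at least as large as the observed
#' error. 1 is the best attainable score (zero error), 0.5 sits at the
#' chance median, 0 at the worst possible error.
#'
#' @param correct,response endpoint angles, degrees.
#' @param radius movement-area radius, vm (default 60).
#' @param chanceDistribution optional precomputed vector of random-agent
#'   single-endpoint errors for this correct endpoint; simulated if NULL.
#' @param nIter simulation size when simulating (default 5000).
#' @param endpointStep circumference step, degrees (default 1).
#' @param seed optional seed for the simulation.
#' @return accuracy in `[0, 1]`.
#' @export
normalizedAccuracy <- function(correct, response, radius = 60,
                               chanceDistribution = NULL, nIter = 5000,
                               endpointStep = 1, seed = NULL) {
  if (is.null(chanceDistribution)) {
    if (!is.null(seed)) set.seed(seed)
    grid <- seq(0, 360 - endpointStep, by = endpointStep)
    draws <- sample(grid, nIter, replace = TRUE)
    chanceDistribution <- chordFromSeparation(
      angularSeparation(draws, correct), radius)
  }
  if (!length(chanceDistribution)) stop("empty chance distribution")
  observed <- chordFromSeparation(angularSeparation(correct, response),
                                  radius)
  mean(chanceDistribution >= observed)
}
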