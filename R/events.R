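#' Default inter-trial jitter sampler
#'
#' Draws the jittered fixation delays separating task phases: discrete
#' seconds on \{2, ..., 7\} with weights (0.05, 0.10, 0.20, 0.25, 0.25,
#' 0.15), giving a mean of exactly 5 s on the stated 2-7 s support.
#'
#' @param k number of draws.
#' @return numeric vector of delays in seconds.
#' @export
defaultJitterSampler <- function(k) {
  sample(2:7, k, replace = TRUE,
         prob = c(0.05, 0.10, 0.20, 0.25, 0.25, 0.15))
}

#' Trial timing parameters
#'
#' @param cue_s cue duration, s (default 2).
#' @param feedback_s feedback duration, s (default 1).
#' @param prePost_s standing lead-in/lead-out around each path, s
#'   (default 1.5).
#' @param jitterSampler function drawing k jittered delays, s.
#' @return list of timing parameters.
#' @export
trialTiming <- function(cue_s = 2, feedback_s = 1, prePost_s = 1.5,
                        jitterSampler = defaultJitterSampler) {
  list(cue_s = cue_s, feedback_s = feedback_s, prePost_s = prePost_s,
       jitterSampler = jitterSampler)
}

emptyEventTable <- function() {
  data.frame(onset = numeric(), duration = numeric(),
             condition = character(), direction = numeric(),
             trial = integer(), segment = integer(), run = integer())
}

eventRow <- function(onset, duration, condition, direction = NA_real_,
                     trial = NA_integer_, segment = NA_integer_,
                     run = NA_integer_) {
  data.frame(onset = onset, duration = duration, condition = condition,
             direction = direction, trial = trial, segment = segment,
             run = run)
}

## event rows of one observed/walked path: lead-in standing, per segment a
## rotation (from the previous heading) then a translation, lead-out
pathBlockRows <- function(t, trialSeg, condition, arena, timing, trial,
                          run) {
  rows <- list(eventRow(t, timing$prePost_s, "standing",
                        trial = trial, run = run))
  t <- t + timing$prePost_s
  heading <- trialSeg$direction[1]   # agent starts facing segment 1
  for (k in seq_len(nrow(trialSeg))) {
    turn <- angularSeparation(heading, trialSeg$direction[k])
    if (turn > 1e-9) {
      rotDur <- turn / arena$rotationSpeed
      rows <- c(rows, list(eventRow(t, rotDur, "rotation",
                                    trial = trial, segment = k,
                                    run = run)))
      t <- t + rotDur
    }
    heading <- trialSeg$direction[k]
    walkDur <- trialSeg$length[k] / arena$walkSpeed
    rows <- c(rows, list(eventRow(t, walkDur, condition,
                                  direction = trialSeg$direction[k],
                                  trial = trial, segment = k, run = run)))
    t <- t + walkDur
  }
  rows <- c(rows, list(eventRow(t, timing$prePost_s, "standing",
                                trial = trial, run = run)))
  t <- t + timing$prePost_s
  list(rows = rows, t = t)
}

#' Schedule the event table of a run
#'
#' Lays out one task run in time: per trial a cue, the observation block
#' (standing lead-in, alternating rotation and translation events per
#' path segment, standing lead-out), a jittered delay, a navigation block
#' mirroring the observation structure (the simulated agent re-walks the
#' same path), feedback, and another jittered delay. Translation rows
#' carry the segment direction.
#'
#' @param run a `RunSchedule` from [generateRunPaths()].
#' @param arena an [arenaSpec()].
#' @param timing a [trialTiming()].
#' @param seed optional seed for the jitter draws.
#' @param includeNavigation add the navigation block (default TRUE).
#' @return An event table (`data.frame`): onset, duration, condition in
#'   \{cue, standing, rotation, obs_translation, nav_translation, delay,
#'   feedback\}, direction (degrees, translation rows only), trial,
#'   segment, run.
#' @examples
#' ev <- scheduleEvents(generateRunPaths(seed = 1), seed = 1)
#' subset(ev, condition == "obs_translation")[1:3, ]
#' @export
scheduleEvents <- function(run, arena = arenaSpec(),
                           timing = trialTiming(), seed = NULL,
                           includeNavigation = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  seg <- run$segments
  t <- 0
  rows <- list()
  for (tr in sort(unique(seg$trial))) {
    trialSeg <- seg[seg$trial == tr, ]
    rows <- c(rows, list(eventRow(t, timing$cue_s, "cue", trial = tr,
                                  run = run$runIndex)))
    t <- t + timing$cue_s
    blk <- pathBlockRows(t, trialSeg, "obs_translation", arena, timing,
                         tr, run$runIndex)
    rows <- c(rows, blk$rows); t <- blk$t
    d1 <- timing$jitterSampler(1)
    rows <- c(rows, list(eventRow(t, d1, "delay", trial = tr,
                                  run = run$runIndex)))
    t <- t + d1
    if (includeNavigation) {
      blk <- pathBlockRows(t, trialSeg, "nav_translation", arena, timing,
                           tr, run$runIndex)
      rows <- c(rows, blk$rows); t <- blk$t
    }
    rows <- c(rows, list(eventRow(t, timing$feedback_s, "feedback",
                                  trial = tr, run = run$runIndex)))
    t <- t + timing$feedback_s
    d2 <- timing$jitterSampler(1)
    rows <- c(rows, list(eventRow(t, d2, "delay", trial = tr,
                                  run = run$runIndex)))
    t <- t + d2
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  validateEventTable(ev)
  ev
}

translationConditions <- function() c("obs_translation", "nav_translation")

validateEventTable <- function(ev) {
  need <- c("onset", "duration", "condition", "direction", "trial",
            "segment", "run")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("event table missing columns: ", paste(miss, collapse = ", "))
  if (is.unsorted(ev$onset)) stop("event onsets must be non-decreasing")
  if (any(ev$duration < 0)) stop("event durations must be >= 0")
  tra <- ev$condition %in% translationConditions()
  if (any(tra & !is.finite(ev$direction)))
    stop("translation rows must carry a direction")
  invisible(ev)
}

#' Total scan duration implied by an event table
#'
#' @param events an event table.
#' @param padding_s tail padding after the last event, s (default 32,
#'   the haemodynamic kernel support).
#' @return duration in seconds.
#' @export
eventsDuration <- function(events, padding_s = 32) {
  max(events$onset + events$duration) + padding_s
}
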