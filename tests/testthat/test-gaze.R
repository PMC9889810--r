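# build a noiseless trace with well-separated planned saccades; the
# pupil is constant so the 1-SD blink rule removes nothing (with a
# white-noise-only pupil the rule flags ~32% of samples by
# construction; in real recordings the SD is blink-dominated)
plannedTrace <- function(onsets, durations, amplitude = 120,
                         directions = NULL, duration_s = 10,
                         blinks = NULL, noiseSd = 0, seed = 1) {
  if (is.null(directions))
    directions <- seq(0, 300, length.out = length(onsets))
  simulateGaze(duration_s,
               saccades = data.frame(onset = onsets,
                                     duration = durations,
                                     amplitude = amplitude,
                                     direction = directions),
               blinks = blinks, noiseSd = noiseSd,
               pupilSd = if (is.null(blinks)) 0 else 1, seed = seed)
}

test_that("blink removal follows the pupil SD rule", {
  g <- simulateGaze(2, pupilSd = 1, seed = 2)
  out <- removeBlinks(g$trace)
  # gaussian pupil noise: about 32% of samples beyond 1 SD
  expect_equal(mean(out$removed), 2 * pnorm(-1), tolerance = 0.1)

  # a planted dropout is removed
  g2 <- simulateGaze(2, blinks = data.frame(onset = 0.5,
                                            duration = 0.1),
                     pupilSd = 1, seed = 3)
  out2 <- removeBlinks(g2$trace)
  blinkIdx <- g2$trace$t >= 0.5 & g2$trace$t < 0.6
  expect_true(all(out2$removed[blinkIdx]))
  expect_equal(mean(out2$removed[!blinkIdx]), 0, tolerance = 0.02)
  expect_error(removeBlinks(g2$trace[0, ]), "empty")
})

test_that("constant gaze yields no saccades", {
  g <- simulateGaze(3, pupilSd = 1, seed = 4)
  expect_equal(nrow(detectSaccades(g$trace)), 0)
})

test_that("planned saccades are recovered exactly on clean traces", {
  sim <- plannedTrace(c(2, 4.5, 7), rep(0.03, 3))
  sac <- detectSaccades(sim$trace)
  expect_equal(nrow(sac), 3)
  expect_true(all(sac$valid))
  expect_true(all(abs(sac$onset - c(2, 4.5, 7)) <= 0.012))
  # direction equals the planned displacement direction
  expect_true(all(angularSeparation(sac$direction,
                                    c(0, 150, 300)) < 2))
})

test_that("sub-threshold excursions are rejected", {
  # an 8 ms excursion is below the 12 ms duration criterion
  sim <- plannedTrace(c(2, 5), c(0.03, 0.008))
  sac <- detectSaccades(sim$trace)
  expect_equal(nrow(sac), 1)
  expect_lt(abs(sac$onset[1] - 2), 0.012)
})

test_that("detection is translation invariant and rotation equivariant", {
  sim <- plannedTrace(c(2, 5), c(0.03, 0.03), directions = c(10, 100))
  s0 <- detectSaccades(sim$trace)
  shifted <- sim$trace
  shifted$x <- shifted$x + 500; shifted$y <- shifted$y - 300
  attr(shifted, "fs") <- attr(sim$trace, "fs")
  s1 <- detectSaccades(shifted)
  expect_equal(s1$onset, s0$onset)
  expect_equal(s1$direction, s0$direction, tolerance = 1e-9)

  rot <- plannedTrace(c(2, 5), c(0.03, 0.03),
                      directions = c(10 + 45, 100 + 45))
  s2 <- detectSaccades(rot$trace)
  expect_equal(angularSeparation(s2$direction, s0$direction),
               rep(45, 2), tolerance = 2)
})

test_that("saccades without a clean pre-onset window are flagged", {
  # second saccade begins 0.1 s after the first ends: dirty window
  sim <- plannedTrace(c(2, 2.13), c(0.03, 0.03))
  sac <- detectSaccades(sim$trace)
  expect_equal(nrow(sac), 2)
  expect_true(sac$valid[1])
  expect_false(sac$valid[2])

  # a blink shortly before onset also invalidates
  sim2 <- plannedTrace(5, 0.03,
                       blinks = data.frame(onset = 4.9,
                                           duration = 0.05))
  sac2 <- detectSaccades(sim2$trace)
  expect_equal(nrow(sac2), 1)
  expect_false(sac2$valid[1])
})

test_that("detector recall and precision on a noiseless fixture", {
  onsets <- seq(1, 17, by = 2)
  sim <- plannedTrace(onsets, rep(0.025, 9), duration_s = 19)
  sac <- detectSaccades(sim$trace)
  hits <- vapply(onsets, function(o)
    any(abs(sac$onset - o) < 0.05), logical(1))
  expect_gte(mean(hits), 0.95)                 # recall
  fp <- vapply(seq_len(nrow(sac)), function(i)
    !any(abs(onsets - sac$onset[i]) < 0.05), logical(1))
  expect_equal(sum(fp), 0)                     # no false positives
})

test_that("saccades map into translation-period grid events", {
  ev <- fixtureEvents
  obs <- ev[ev$condition == "obs_translation", ]
  # one saccade inside the first translation, one in the gap before it
  sac <- data.frame(onset = c(obs$onset[1] + 0.5, obs$onset[1] - 1),
                    duration = 0.03, direction = c(123, 45),
                    amplitude = 100, peakSpeed = 1, valid = TRUE)
  out <- saccadesToEvents(sac, ev)
  expect_equal(nrow(out), 1)
  expect_equal(out$direction, 123)
  expect_equal(out$condition, "obs_translation")
  expect_equal(out$trial, obs$trial[1])
  # invalid saccades are dropped by default
  sac$valid <- FALSE
  expect_equal(nrow(saccadesToEvents(sac, ev)), 0)
  expect_equal(nrow(saccadesToEvents(sac[0, ], ev)), 0)
})

test_that("AOI coverage counts samples inside the active polygon", {
  g <- simulateGaze(1, pupilSd = 0)
  box <- function(cx, cy, w) cbind(x = cx + c(-w, w, w, -w),
                                   y = cy + c(-w, -w, w, w))
  inAoi <- list(window = c(0, 1), polygon = box(0, 0, 10))
  outAoi <- list(window = c(0, 1), polygon = box(100, 100, 10))
  expect_equal(aoiCoverage(g$trace, list(inAoi))$pctInside, 100)
  expect_equal(aoiCoverage(g$trace, list(outAoi))$pctInside, 0)

  # 70%-inside fixture by construction: gaze inside for 0.7 s of 1 s
  tr <- g$trace
  tr$x[tr$t >= 0.7] <- 100
  expect_equal(aoiCoverage(tr, list(inAoi))$pctInside, 70,
               tolerance = 0.01)
  expect_error(aoiCoverage(g$trace, list()), "no AOI")
})
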