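test_that("chord geometry matches closed forms", {
  g <- chordGeometry(0, 180, 60)
  expect_equal(g$length, 120)
  expect_equal(g$direction, 180)

  g <- chordGeometry(0, 90, 60)
  expect_equal(g$length, 2 * 60 * sin(pi / 4), tolerance = 1e-9)
  expect_equal(g$direction, 135, tolerance = 1e-9)
  # coordinate-subtraction cross-check
  s <- angleToXY(0, 60); e <- angleToXY(90, 60)
  expect_equal(g$length, sqrt(sum((e - s)^2)), tolerance = 1e-9)

  expect_error(chordGeometry(0, 0, 60), "degenerate")
  expect_error(chordGeometry(10, 370, 60), "degenerate")
})

test_that("directional bins cover the circle in both modes", {
  sch <- directionScheme()
  expect_identical(binOfDirection(c(5, 65, 359), sch), c(0, 1, 5))
  expect_identical(binOfDirection(c(0, 59.9, 60), sch), c(0, 0, 1))
  # residue classes: directions 60 degrees apart share a bin
  res <- directionScheme(binMode = "residue")
  expect_identical(binOfDirection(c(10, 70, 130, 190), res),
                   rep(1, 4))
  expect_equal(sort(unique(binOfDirection(res$directions, res))), 0:5)
  # each bin holds 6 of the 36 directions in both modes
  expect_true(all(table(binOfDirection(sch$directions, sch)) == 6))
  expect_true(all(table(binOfDirection(res$directions, res)) == 6))
})

test_that("invalid arena and scheme parameters are rejected", {
  expect_error(arenaSpec(movementRadius = 90, observationRadius = 60))
  expect_error(arenaSpec(nSectors = 2))
  expect_error(directionScheme(nDirections = 35))
})

test_that("generated runs satisfy all balancing constraints", {
  sch <- directionScheme()
  for (seed in 1:25) {
    run <- generateRunPaths(seed = seed)
    seg <- run$segments
    expect_equal(nrow(seg), 36)
    # every bin used exactly 6 times
    expect_true(all(table(seg$bin) == 6))
    # three pairwise-distinct bins per trial
    expect_true(all(tapply(seg$bin, seg$trial,
                           function(b) length(unique(b))) == 3))
    # directions come from the 36-direction scheme and match their bin
    expect_true(all(seg$direction %in% sch$directions))
    expect_identical(binOfDirection(seg$direction, sch),
                     as.numeric(seg$bin))
    # segments chain: end of k = start of k+1
    for (tr in 1:12) {
      s <- seg[seg$trial == tr, ]
      expect_equal(s$startAngle[-1], s$endAngle[-3], tolerance = 1e-9)
    }
    # sector rule: endpoints neither in the same nor adjacent sectors
    expect_true(all(sectorDistance(seg$startSector, seg$endSector,
                                   6) >= 2))
    # chord lengths within the admissible band
    expect_true(all(seg$length >= 60 & seg$length <= 120))
    # each sector hosts a trial start exactly twice
    expect_true(all(table(seg$startSector[seg$segment == 1]) == 2))
    # stated geometry is self-consistent
    g <- chordGeometry(seg$startAngle, seg$endAngle, 60)
    expect_equal(g$length, seg$length, tolerance = 1e-9)
    expect_equal(g$direction, seg$direction, tolerance = 1e-6)
  }
})

test_that("path generation is deterministic under a fixed seed", {
  r1 <- generateRunPaths(seed = 7)
  r2 <- generateRunPaths(seed = 7)
  expect_identical(r1$segments, r2$segments)
})

test_that("event schedule lays trials out with the stated timing", {
  run <- fixtureRun
  arena <- arenaSpec()
  ev <- scheduleEvents(run, arena, seed = 5)
  expect_false(is.unsorted(ev$onset))
  expect_true(all(ev$duration >= 0))

  obs <- ev[ev$condition == "obs_translation", ]
  nav <- ev[ev$condition == "nav_translation", ]
  expect_equal(nrow(obs), 36)
  expect_equal(nrow(nav), 36)
  # translation duration = length / walk speed, never above 8 s
  seg <- run$segments[order(run$segments$trial, run$segments$segment), ]
  expect_equal(obs$duration, seg$length / arena$walkSpeed,
               tolerance = 1e-9)
  expect_true(all(obs$duration <= 8 + 1e-9))
  expect_true(all(obs$duration >= 4 - 1e-9))
  # a 120 vm segment takes 8 s at 15 vm/s
  expect_equal(120 / arena$walkSpeed, 8)
  # rotation duration = turn angle / rotation speed (90 deg -> 1.8 s)
  expect_equal(90 / arena$rotationSpeed, 1.8)
  rot <- ev[ev$condition == "rotation", ]
  expect_true(all(rot$duration <= 180 / arena$rotationSpeed + 1e-9))
  # cue and feedback rows once per trial at the stated durations
  expect_true(all(ev$duration[ev$condition == "cue"] == 2))
  expect_true(all(ev$duration[ev$condition == "feedback"] == 1))
})

test_that("jitter sampler has mean 5 s on support [2, 7]", {
  set.seed(1)
  draws <- defaultJitterSampler(20000)
  expect_true(all(draws >= 2 & draws <= 7))
  expect_equal(mean(draws), 5, tolerance = 0.02)
  # exact expectation of the discrete sampler
  expect_equal(sum(2:7 * c(0.05, 0.10, 0.20, 0.25, 0.25, 0.15)), 5)
})

test_that("cumulative distance error matches chord closed forms", {
  expect_equal(cumulativeDistanceError(c(0, 120, 240), c(0, 120, 240)),
               0)
  expect_equal(cumulativeDistanceError(c(0, 120, 240),
                                       c(180, 300, 60)), 120)
  expect_equal(cumulativeDistanceError(c(0, 120, 240),
                                       c(90, 120, 240)),
               2 * 60 * sin(pi / 4) / 3, tolerance = 1e-9)
  # symmetric and bounded by the diameter
  set.seed(2)
  for (i in 1:20) {
    a <- runif(3, 0, 360); b <- runif(3, 0, 360)
    e <- cumulativeDistanceError(a, b)
    expect_equal(e, cumulativeDistanceError(b, a))
    expect_gte(e, 0); expect_lte(e, 120)
  }
  expect_error(cumulativeDistanceError(c(0, 1), c(0, 1, 2)), "length")
})

test_that("random-agent error distribution has the closed-form mean and is endpoint-invariant", {
  # uniform endpoints give a mean chord of 4r/pi regardless of target
  chA <- randomAgentChance(matrix(c(0, 120, 240), 1), nIter = 4000,
                           seed = 11)
  chB <- randomAgentChance(matrix(c(33, 77, 301), 1), nIter = 4000,
                           seed = 12)
  expect_equal(mean(chA$distribution), 4 * 60 / pi, tolerance = 0.02)
  expect_equal(mean(chB$distribution), 4 * 60 / pi, tolerance = 0.02)
  expect_equal(mean(chA$distribution), mean(chB$distribution),
               tolerance = 0.03)
  expect_equal(chA$chance, chB$chance, tolerance = 0.06)
  expect_lte(chA$chance, 120)
  expect_error(randomAgentChance(matrix(0, 1, 3), nIter = 0), "nIter")
})

test_that("normalized accuracy is a percentile rank of the chance error", {
  dist <- chordFromSeparation(angularSeparation(0:359, 40), 60)
  expect_equal(normalizedAccuracy(40, 40, chanceDistribution = dist), 1)
  expect_lte(normalizedAccuracy(40, 220, chanceDistribution = dist),
             1 / 360 + 1e-9)  # antipodal: worst possible
  med <- normalizedAccuracy(40, 40 + 90, chanceDistribution = dist)
  expect_equal(med, 0.5, tolerance = 0.02)
  expect_error(normalizedAccuracy(0, 0, chanceDistribution = numeric()),
               "empty")
})

test_that("distance walked shows no systematic bin effect", {
  rows <- do.call(rbind, lapply(1:20, function(s) {
    seg <- generateRunPaths(seed = 300 + s)$segments
    data.frame(run = s, bin = factor(0:5),
               dist = as.numeric(tapply(seg$length, seg$bin, sum)))
  }))
  p <- summary(stats::aov(dist ~ bin, rows))[[1]][["Pr(>F)"]][1]
  expect_gt(p, 0.01)
})
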