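test_that("quadrature and alignment modulators are exact", {
  expect_equal(makeQuadratureModulators(0, 6)[1, ],
               c(sin = 0, cos = 1))
  expect_equal(makeQuadratureModulators(15, 6)[1, ],
               c(sin = 1, cos = 0))
  expect_equal(makeQuadratureModulators(45, 4)[1, ],
               c(sin = 0, cos = -1))
  expect_equal(alignmentModulator(37, 37, 6), 1)
  expect_equal(alignmentModulator(67, 37, 6), -1)
  expect_equal(alignmentModulator(52, 37, 6), 0)
})

test_that("orientation estimation handles all quadrants", {
  expect_equal(estimateOrientation(0, 1, 6)$phi, 0)
  expect_equal(estimateOrientation(1, 0, 6)$phi, 15)
  expect_equal(estimateOrientation(-1, 0, 6)$phi, 45)
  expect_equal(estimateOrientation(0, -1, 6)$phi, 30)
  # voxel-wise output follows the same formula per voxel
  out <- estimateOrientation(c(1, 0, 2), c(0, 1, 0), 6)
  expect_equal(out$voxelPhi, c(15, 0, 15))
  expect_error(estimateOrientation(c(1, -1), c(0, 0), 6), "undefined")
})

test_that("orientation matches a brute-force cosine-fit grid search", {
  set.seed(8)
  alpha <- seq(0, 350, by = 10)
  for (rep in 1:10) {
    phiTrue <- runif(1, 0, 60)
    amp <- cos(6 * (alpha - phiTrue) * pi / 180) + rnorm(36, 0, 0.3)
    # quadrature regression route
    quad <- makeQuadratureModulators(alpha, 6)
    b <- coef(lm(amp ~ quad))
    phiHat <- estimateOrientation(b["quadsin"], b["quadcos"], 6)$phi
    # independent oracle: grid search minimizing SSE of the cosine fit
    # with a non-negative modulation amplitude (a free negative slope
    # would alias phi and phi + 30)
    grid <- seq(0, 60, by = 0.01)
    sse <- vapply(grid, function(p) {
      m <- cos(6 * (alpha - p) * pi / 180)
      fit <- lm(amp ~ m)
      if (coef(fit)["m"] < 0) Inf else sum(fit$residuals^2)
    }, numeric(1))
    phiGrid <- grid[which.min(sse)]
    expect_lt(fundamentalDifference(phiHat, phiGrid, 6), 0.02)
  }
})

test_that("MAD outlier rule keeps and drops the right values", {
  keep <- madOutlierFilter(c(1:9, 100))
  expect_identical(keep, c(rep(TRUE, 9), FALSE))
  expect_true(all(madOutlierFilter(rep(4, 5))))
  expect_true(all(madOutlierFilter(c(-1, 0, 1))))
  expect_error(madOutlierFilter(numeric()), "empty")
})

test_that("segment magnitudes follow the fold beta and alignment", {
  expect_equal(segmentwiseMagnitudes(1, 10, 10, 6), 1)
  expect_equal(segmentwiseMagnitudes(2, 10, 40, 6), -2)
  d <- c(0, 25, 40)
  expect_equal(segmentwiseMagnitudes(1.5, 12, d, 6, "fold_beta"),
               rep(1.5, 3))
  m <- segmentwiseMagnitudes(1.5, 12, d, 6)
  expect_equal(mean(m), 1.5 * mean(alignmentModulator(d, 12, 6)))
})

test_that("magnitude-modulated design centers and differences events", {
  ev <- fixtureEvents
  nTrans <- sum(ev$condition == "obs_translation")
  # constant magnitudes vanish after centering
  X <- buildMagnitudeModulatedDesign(ev, rep(2, nTrans), fixtureTr,
                                     fixtureVolumes)
  expect_lt(max(abs(X$matrix[, "gridMagnitude"])), 1e-12)
  expect_error(buildMagnitudeModulatedDesign(ev, 1:3, fixtureTr,
                                             fixtureVolumes),
               "one magnitude per")

  # two events with +1/-1: the modulator is the boxcar difference
  ev2 <- rbind(eventRow(10, 4, "obs_translation", 0, 1, 1, 1),
               eventRow(40, 4, "obs_translation", 90, 1, 2, 1))
  X2 <- buildMagnitudeModulatedDesign(ev2, c(1, -1), 1, 100)
  one <- buildDesign(eventRow(10, 4, "obs_translation", 0, 1, 1, 1),
                     1, 100)$matrix[, "obs_translation"]
  two <- buildDesign(eventRow(40, 4, "obs_translation", 90, 1, 2, 1),
                     1, 100)$matrix[, "obs_translation"]
  expect_equal(X2$matrix[, "gridMagnitude"], one - two,
               tolerance = 1e-9)
  # full-rank design on real synthetic magnitudes
  set.seed(9)
  X3 <- buildMagnitudeModulatedDesign(ev, rnorm(nTrans), fixtureTr,
                                      fixtureVolumes)
  expect_equal(qr(X3$matrix)$rank, ncol(X3$matrix))
})

test_that("noiseless CV analysis recovers the planted orientation", {
  ts <- makeBold(phi = 23, amplitude = 1, nVoxels = 3)
  res <- runCvGridAnalysis(fixtureEvents, ts, symmetry = 6,
                           condition = "observation")
  phis <- foldOrientations(res)
  expect_true(all(fundamentalDifference(phis, 23, 6) < 1))
  expect_gt(subjectMagnitude(res), 0)
  # per-segment magnitudes carry one row per held-out segment
  expect_equal(nrow(segmentMagnitudes(res)), 36)
  # independent oracle: regressing the known event amplitudes on the
  # alignment modulator at the true orientation gives slope 1
  dirs <- fixtureEvents$direction[
    fixtureEvents$condition == "obs_translation"]
  amp <- 1 + cos(6 * (dirs - 23) * pi / 180)
  slope <- coef(lm(amp ~ alignmentModulator(dirs, 23, 6)))[2]
  expect_equal(unname(slope), 1, tolerance = 1e-9)
})

test_that("folds with congruent held-out directions are skipped", {
  # trial 1 directions are all congruent modulo 60: its alignment
  # modulator has no variance at 6-fold and the fold must be dropped
  dirs <- list(c(10, 70, 130), c(0, 50, 100), c(20, 90, 150),
               c(30, 80, 140))
  rows <- list()
  t0 <- 0
  for (tr in 1:4) for (k in 1:3) {
    rows <- c(rows, list(eventRow(t0, 5, "obs_translation",
                                  dirs[[tr]][k], tr, k, 1)))
    t0 <- t0 + 12
  }
  ev <- do.call(rbind, rows)
  ts <- simulateRoiBold(ev, groundTruth(phi = 23, amplitude = 1),
                        noiseSpec(), tr = 2, nVoxels = 2)
  expect_warning(
    res <- runCvGridAnalysis(ev, ts, 6, condition = "observation"),
    "congruent")
  expect_false(is.finite(foldBetas(res)[1, 1]))
  # three non-degenerate folds contribute 9 segment rows
  expect_equal(nrow(segmentMagnitudes(res)), 9)
  expect_true(is.finite(subjectMagnitude(res)))
})

test_that("fold and voxel averaging commute", {
  ts <- makeBold(phi = 40, amplitude = 1, whiteSd = 0.5, nVoxels = 4,
                 seed = 10)
  res <- runCvGridAnalysis(fixtureEvents, ts, symmetry = 6,
                           condition = "observation")
  B <- foldBetas(res)
  expect_equal(mean(colMeans(B)), mean(rowMeans(B)), tolerance = 1e-12)
  expect_equal(subjectMagnitude(res), mean(B), tolerance = 1e-12)
})

test_that("analysis is equivariant to a common rotation of directions", {
  delta <- 20
  ts <- makeBold(phi = 10, amplitude = 1, nVoxels = 2)
  # rotating all directions and the true orientation together leaves
  # the BOLD data untouched, so the same series serves both analyses
  evRot <- fixtureEvents
  sel <- !is.na(evRot$direction)
  evRot$direction[sel] <- wrapDegrees(evRot$direction[sel] + delta)
  res0 <- runCvGridAnalysis(fixtureEvents, ts, 6,
                            condition = "observation")
  res1 <- runCvGridAnalysis(evRot, ts, 6, condition = "observation")
  shift <- fundamentalDifference(foldOrientations(res1),
                                 wrapFundamental(
                                   foldOrientations(res0) + delta, 6),
                                 6)
  expect_true(all(shift < 0.2))
  expect_equal(subjectMagnitude(res1), subjectMagnitude(res0),
               tolerance = 0.02)
})

test_that("orientation transfer test tracks shared and shifted codes", {
  ts <- makeBold(phi = 23, amplitude = 1, nVoxels = 2)
  tt <- orientationTransferTest(23, fixtureEvents, ts, 6,
                                condition = "observation")
  expect_equal(tt$magnitude, 1, tolerance = 0.05)
  # a 30-degree offset flips the sign of the alignment
  tt30 <- orientationTransferTest(wrapFundamental(23 + 30, 6),
                                  fixtureEvents, ts, 6,
                                  condition = "observation")
  expect_lt(tt30$magnitude, 0)
})

test_that("voxelwise variant estimates per-voxel orientations", {
  ts <- makeBold(phi = 23, amplitude = 1, nVoxels = 3)
  res <- runCvGridAnalysis(fixtureEvents, ts, 6,
                           condition = "observation",
                           voxelwise = TRUE)
  expect_true(all(fundamentalDifference(res@voxelPhi, 23, 6) < 1))
  expect_gt(subjectMagnitude(res), 0)
})

test_that("group summary handles edge cases and applies the MAD rule", {
  z <- groupSummary(rep(0, 10))
  expect_equal(z$t, 0); expect_equal(z$p, 0.5)
  cst <- groupSummary(rep(1, 4))
  expect_true(cst$significant); expect_lt(cst$p, 1e-12)
  # the MAD rule drops the planted outlier before testing
  g <- groupSummary(c(rnorm(20, 1, 0.1), 50), bonferroniM = 6)
  expect_equal(sum(!g$kept), 1)
  expect_equal(g$n, 20)
  expect_equal(g$alphaAdjusted, 0.05 / 6)
  expect_error(groupSummary(c(1)), "fewer than 2")
})

test_that("cv schemes partition trials as requested", {
  expect_equal(length(cvScheme("loto", 12)), 12)
  expect_equal(cvScheme("half", 12), list(1:6, 7:12))
  parts <- cvScheme("parts", 12, k = 4)
  expect_equal(length(parts), 4)
  expect_equal(sort(unlist(parts)), 1:12)
})
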