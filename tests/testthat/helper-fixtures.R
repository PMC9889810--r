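# Shared fixtures, built in code at load time. One observation-only run
# keeps the GLM fits fast while exercising the full pipeline. Seed 106
# gives a schedule in which no trial's three directions are congruent
# modulo 60 or 90 degrees, so no CV fold is degenerate at the 6- or
# 4-fold symmetries (degenerate-fold handling has its own test).

fixtureRun <- generateRunPaths(seed = 106)
fixtureEvents <- scheduleEvents(fixtureRun, seed = 106,
                                includeNavigation = FALSE)
fixtureEventsNav <- scheduleEvents(fixtureRun, seed = 102)
fixtureTr <- 2.029
fixtureVolumes <- ceiling(eventsDuration(fixtureEvents) / fixtureTr)

# simulate an ROI series on the shared schedule
makeBold <- function(phi = 23, amplitude = 1, whiteSd = 0, ar1 = 0,
                     nVoxels = 4, seed = NULL, voxelJitterSd = 0,
                     events = fixtureEvents, symmetry = 6,
                     driftAmplitude = 0) {
  simulateRoiBold(events,
                  groundTruth(phi = phi, symmetry = symmetry,
                              amplitude = amplitude,
                              voxelJitterSd = voxelJitterSd),
                  noiseSpec(whiteSd = whiteSd, ar1 = ar1,
                            driftAmplitude = driftAmplitude),
                  tr = fixtureTr, nVolumes = fixtureVolumes,
                  nVoxels = nVoxels, seed = seed)
}

# mean circular error (degrees, in the n-fold domain) of fold
# orientations against a known truth
foldPhiError <- function(res, phiTrue, n = 6) {
  phis <- foldOrientations(res)
  mean(fundamentalDifference(phis[is.finite(phis)], phiTrue, n))
}
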