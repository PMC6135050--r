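test_that("test CSD distributions have the declared structure and conserve current", {
  # fine cases: 0/1 on 10 bins
  for (k in 1:7) {
    tc <- makeTestCSD(k)
    expect_s4_class(tc, "TestCase")
    expect_true(all(tc@values %in% c(0, 1)))
    expect_length(tc@values, 10)
  }
  # case 1 covers exactly the proximal coarse compartment (bins 1-2),
  # case 7 exactly the second coarse compartment (bins 3-5)
  expect_equal(which(makeTestCSD(1)@values == 1), 1:2)
  expect_equal(which(makeTestCSD(7)@values == 1), 3:5)
  # strip cases: density x area conserved (case 9 halves the window,
  # case 10 halves the lateral extent; both double the density)
  t8 <- makeTestCSD(8); t9 <- makeTestCSD(9); t10 <- makeTestCSD(10)
  area <- function(tc) diff(tc@window) * tc@lateralScale * tc@density
  expect_equal(area(t9), area(t8))
  expect_equal(area(t10), area(t8))
  expect_equal(t10@window, t8@window)  # same axial window as case 8
  expect_equal(t9@window[2], t8@window[2] / 2)
  expect_error(makeTestCSD(11), "1..10")
  expect_error(makeTestCSD(0), "1..10")
})

test_that("fine-model windows align bins 1-2 and 3-5 with the coarse compartments", {
  fm <- fineModel10()
  cm <- zcucModel()
  wf <- compartmentWindows(fm); wc <- compartmentWindows(cm)
  expect_equal(wf[2, 2], wc[1, 2], tolerance = 1e-12)
  expect_equal(wf[5, 2], wc[2, 2], tolerance = 1e-12)
})

test_that("matching-compartment sources are recovered exactly; mismatched ones are biased", {
  fm <- fineModel10()
  coarse <- c(0, 1/3, 2/3, 1)
  # cases 1 and 7: the fine source equals a coarse compartment; the
  # estimate is the source's surface-density seen at coarse resolution
  for (spec in list(list(case = 1, comp = 1), list(case = 7, comp = 2))) {
    est <- csdValues(runRoundtrip(makeTestCSD(spec$case), fm, coarse)$csd)
    expect_equal(est[spec$comp], 1, tolerance = 1e-6)
    expect_equal(est[-spec$comp], rep(0, 3), tolerance = 1e-6)
  }
  # sub-compartment sources (2, 3, 6): reverse polarity in a neighbor
  for (k in c(2, 3, 6)) {
    est <- csdValues(runRoundtrip(makeTestCSD(k), fm, coarse)$csd)
    hit <- which.max(est)
    expect_gt(est[hit], 0)
    neighbors <- intersect(c(hit - 1, hit + 1), 1:4)
    expect_lt(min(est[neighbors]), 0)
  }
  # supra-compartment sources (4, 5): same-sign detection in every
  # overlapped compartment
  overlap <- list(`4` = 1:2, `5` = 2:3)
  for (k in c(4, 5)) {
    est <- csdValues(runRoundtrip(makeTestCSD(k), fm, coarse)$csd)
    expect_true(all(est[overlap[[as.character(k)]]] > 0))
  }
})

test_that("a matched-resolution roundtrip is exact", {
  m <- zcucModel()
  set.seed(21)
  csd <- rnorm(4)
  rt <- runRoundtrip(csd, m, c(0, 1/3, 2/3, 1))
  expect_equal(csdValues(rt$csd), csd, tolerance = 1e-9)
  expect_error(runRoundtrip(makeTestCSD(2), fineModel10(), c(0, 0.25, 0.5, 1)),
               "does not coincide")
  expect_error(runRoundtrip(makeTestCSD(8), fineModel10(), c(0, 1)),
               "caseRatioReport")
})

test_that("coarse-model artifacts shrink as the coarse resolution approaches the fine one", {
  g <- speciesGeometry("Zcuc")
  fm <- fineModel10()
  tc <- makeTestCSD(4)  # supra-compartment block on bins 1-4
  err <- sapply(list(c(0, 1/3, 2/3, 1), seq(0, 1, length.out = 10)),
                function(pos) {
    rt <- runRoundtrip(tc, fm, pos)
    est <- csdValues(rt$csd)
    # compare against the fine profile averaged over the coarse windows
    wc <- compartmentWindows(rt$coarseModel)
    wf <- compartmentWindows(fm)
    ref <- vapply(seq_len(nrow(wc)), function(i) {
      ov <- pmax(0, pmin(wf[, 2], wc[i, 2]) - pmax(wf[, 1], wc[i, 1]))
      sum(ov * tc@values) / sum(ov)
    }, numeric(1))
    max(abs(est - ref))
  })
  expect_lt(err[2], 1e-9)      # matched resolution: exact
  expect_gt(err[1], 1e-3)      # coarse: visibly biased
})

test_that("case ratios show proximal concentration effects in the expected directions", {
  for (wl in c(0.3, 0.45, 0.6)) for (mode in c("printed", "half")) {
    g <- antennaGeometry("sweep", length = 1, width = wl)
    r <- caseRatioReport(g, mode)
    # concentrating the same current closer to the proximal electrode
    # raises its EAG; case 10 (lateral concentration) raises it more
    expect_gt(r[["case10_eagProximal"]], r[["case9_eagProximal"]])
    expect_gt(r[["case9_eagProximal"]], 100)
    # the second electrode loses signal in case 9, gains in case 10
    expect_lt(r[["case9_eagSecond"]], 100)
    expect_gt(r[["case10_eagSecond"]], 100)
    # both concentrations inflate the proximal CSD estimate
    expect_gt(r[["case9_csdProximal"]], 100)
    expect_gt(r[["case10_csdProximal"]], 100)
  }
})

test_that("the random-activation experiment produces the expected regression structure", {
  res <- randomActivationExperiment(nSims = 120, seed = 2)
  expect_equal(dim(res$density), c(120, 4))
  expect_equal(length(stats::fitted(res$fitCSD)), 480)  # 4 points per simulation
  expect_gt(res$r2CSD, res$r2EAG)
  expect_lt(res$interceptCSD, 0)
  expect_gt(res$interceptEAG, 0)
  # robust to the activation distribution
  resE <- randomActivationExperiment(nSims = 120, seed = 2,
                                     activation = "exponential")
  expect_gt(resE$r2CSD, resE$r2EAG)
  # deterministic for a fixed seed
  res2 <- randomActivationExperiment(nSims = 120, seed = 2)
  expect_identical(res$csd, res2$csd)
  expect_error(randomActivationExperiment(nSims = 1), "at least 2")
})

test_that("electrode subsets preserve the main response features and bias small ones", {
  g <- speciesGeometry("Zcuc")
  m7 <- buildModel(g, seq(0, 1, length.out = 7))
  time <- seq(0, 3.998, by = 1 / 500)
  onset <- 1
  # two distinct sinks: mid-funiculus (compartment 4, x = 0.5) and the
  # distal tip (compartment 7) -- the two-sink pattern that merges when
  # sampled with too few electrodes
  csd <- twoSinkCSD(length(time), time, onset)
  rec <- synthesizeRecording(m7, csd, onset = onset, t0 = 0)
  res <- subsetAnalysis(rec, g)
  # full array localizes the stronger sink in compartment 4 and resolves
  # both sinks as separate active regions
  expect_equal(which.max(res$n7_1234567$areas), 4)
  expect_gt(res$n7_1234567$areas[7], 0.5 * max(res$n7_1234567$areas))
  actives7 <- res$n7_1234567$areas > 0.25 * max(res$n7_1234567$areas)
  expect_false(all(diff(which(actives7)) == 1))
  # 4 electrodes: the response is no longer divided into two distinct
  # sinks -- one contiguous active region remains
  actives4 <- res$n4_1357$areas > 0.25 * max(res$n4_1357$areas)
  expect_true(all(diff(which(actives4)) == 1))
  # size-2 models drag the center of mass toward one electrode position
  com7 <- res$n7_1234567$centerOfMass
  for (v in list(res$n2_14, res$n2_47)) {
    pos <- electrodePositions(v$model)
    expect_lt(min(abs(v$centerOfMass - pos)), min(abs(com7 - pos)))
  }
  expect_error(subsetAnalysis(rec, g, subsetSizes = 5), "size 5")
})

test_that("4-electrode subsampling keeps the compartment of maximal response", {
  g <- speciesGeometry("Zcuc")
  m7 <- buildModel(g, seq(0, 1, length.out = 7))
  time <- seq(0, 3.998, by = 1 / 500)
  onset <- 1
  # dominant sink squarely inside compartment 3 (x = 1/3), secondary distal
  csd <- twoSinkCSD(length(time), time, onset, sinks = c(3, 7),
                    amps = c(-1, -0.4))
  rec <- synthesizeRecording(m7, csd, onset = onset, t0 = 0)
  res <- subsetAnalysis(rec, g, subsetSizes = c(4, 7))
  expect_equal(which.max(res$n7_1234567$areas), 3)
  # x = 1/3 lies in compartment 2 of the 4-position model
  expect_equal(which.max(res$n4_1357$areas), 2)
  # the centers of mass point to the same antennal region
  expect_lt(abs(res$n4_1357$centerOfMass - res$n7_1234567$centerOfMass), 0.1)
})

test_that("geometry choice shifts CSD amplitudes but not the peak compartment", {
  m <- zcucModel()
  phi <- predictEAG(m, c(0, -1, 0, 0))  # single-peak EAG distribution
  sweep <- geometrySweep(phi, speciesPresets())
  expect_true(all(sweep$peakCompartment == sweep$peakCompartment[1]))
  # cylinder vs both 3:1 cones with equal mean diameter
  geos <- list(
    cyl = antennaGeometry("cyl", 1, 0.3),
    coneDec = antennaGeometry("dec", 1, 0.3, shape = "cone", taperRatio = 1/3),
    coneInc = antennaGeometry("inc", 1, 0.3, shape = "cone", taperRatio = 3))
  sw <- geometrySweep(phi, geos)
  expect_true(all(sw$peakCompartment == sw$peakCompartment[1]))
  peak <- sw$peakCompartment[1]
  expect_gt(diff(range(sw$csd[, peak])) / abs(mean(sw$csd[, peak])), 0.01)
  # where the response actually lives (the peak compartment and the
  # proximal compartment carrying its return current), the response level
  # anticorrelates with the modeled compartment surface; remote artifact
  # compartments carry no such relation
  expect_lt(stats::cor(abs(sw$csd[, peak]), sw$compartmentSurface[, peak]), 0)
  expect_lt(stats::cor(-sw$csd[, 1], sw$compartmentSurface[, 1]), 0)
})

test_that("synthesized recordings are deterministic and exactly invertible without noise", {
  m <- zcucModel()
  time <- seq(0, 2.998, by = 1 / 500)
  csd <- matrix(0, length(time), 4)
  csd[time > 1, 2] <- -1
  recA <- synthesizeRecording(m, csd, onset = 1, noiseSd = 0.05, seed = 4, t0 = 0)
  recB <- synthesizeRecording(m, csd, onset = 1, noiseSd = 0.05, seed = 4, t0 = 0)
  expect_identical(recordingTraces(recA), recordingTraces(recB))
  rec0 <- synthesizeRecording(m, csd, onset = 1, noiseSd = 0, t0 = 0)
  map <- estimateCSDTimeseries(m, rec0)
  expect_equal(csdMapValues(map), csd, tolerance = 1e-9)
  expect_error(synthesizeRecording(m, csd, noiseSd = -1), "non-negative")
})

test_that("noise propagates to the CSD estimate according to the inverse rows", {
  # with phi = F C + e, e ~ N(0, s^2 I): sd(C_i) = s * ||Finv[i, ]||
  m <- zcucModel()
  Fi <- invertTransfer(transferMatrix(m))
  s <- 0.02
  analytic <- s * sqrt(rowSums(Fi^2))
  nT <- 4000
  csd <- matrix(0, nT, 4)
  rec <- synthesizeRecording(m, csd, noiseSd = s, seed = 8, t0 = 0)
  est <- csdMapValues(estimateCSDTimeseries(m, rec))
  empirical <- apply(est, 2, stats::sd)
  expect_equal(empirical, analytic, tolerance = 0.08)
  # the outer compartments have the larger inverse row norms and hence the
  # noisier estimates
  expect_gt(mean(empirical[c(1, 4)]), mean(empirical[2:3]))
})
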