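## Bias-characterization machinery: artificial CSD distributions,
## fine-to-coarse roundtrips, electrode-subset analysis, geometry
## sensitivity, the random-activation experiment and a synthetic
## recording generator.

## 10-bin layouts of the qualitative test cases, on the windows of a
## 10-electrode fine model whose bins 1-2 coincide exactly with the
## proximal compartment of the 4-electrode model and bins 3-5 with its
## second compartment.  The layouts are read from the published panels;
## downstream assertions are on sign patterns, not bin-exact equality.
fineCaseBins <- list(
  `1` = 1:2, `2` = 1L, `3` = 4L, `4` = 1:4, `5` = 3:6, `6` = 5L, `7` = 3:5
)

#' Artificial CSD test distributions
#'
#' Cases 1-7: 0/1 profiles on a 10-compartment fine model, probing sources
#' that match a model compartment exactly (1, 7), are smaller than one
#' (2, 3, 6) or span several (4, 5).  Cases 8-10: quantitative strips on
#' the proximal compartment of a 4-compartment model, all carrying the same
#' total current: density 1 on the full compartment (8), density 2 on its
#' proximal half along the axis (9), or density 2 on its central half
#' obtained by halving the source-strip diameter (10).
#'
#' @param caseId integer in 1..10.
#' @return a [TestCase-class].
#' @examples
#' makeTestCSD(9)
#' @export
makeTestCSD <- function(caseId) {
  caseId <- as.integer(caseId)
  if (length(caseId) != 1 || is.na(caseId) || caseId < 1 || caseId > 10)
    stop("caseId must be an integer in 1..10")
  if (caseId <= 7) {
    v <- numeric(10); v[fineCaseBins[[as.character(caseId)]]] <- 1
    return(new("TestCase", caseId = caseId, kind = "fine", values = v,
               window = numeric(), density = 1, lateralScale = 1,
               description = sprintf("0/1 profile on 10 fine compartments (bins %s active)",
                                     paste(which(v == 1), collapse = ","))))
  }
  switch(as.character(caseId),
    "8" = new("TestCase", caseId = 8L, kind = "strip", values = numeric(),
              window = c(0, 1 / 6), density = 1, lateralScale = 1,
              description = "density 1 on the full proximal compartment"),
    "9" = new("TestCase", caseId = 9L, kind = "strip", values = numeric(),
              window = c(0, 1 / 12), density = 2, lateralScale = 1,
              description = "density 2 on the proximal half of the proximal compartment"),
    "10" = new("TestCase", caseId = 10L, kind = "strip", values = numeric(),
               window = c(0, 1 / 6), density = 2, lateralScale = 0.5,
               description = "density 2 on the central half (source-strip diameter halved)"))
}

setMethod("show", "TestCase", function(object) {
  cat(sprintf("TestCase %d (%s): %s\n", object@caseId, object@kind,
              object@description))
})

#' Forward-project a test case and invert it at coarse resolution
#'
#' The fine model computes the EAG distribution generated by the test CSD;
#' the potentials at the coarse electrode positions (which must coincide
#' with fine electrode positions) are then inverted with a coarse model
#' built on those positions, exposing the biases induced by
#' compartmentalization.
#'
#' @param testCase a [TestCase-class] of kind \code{"fine"} (cases 1-7) or
#'   a numeric CSD profile on the fine model's compartments.
#' @param fineModel the fine [CompartmentModel-class] (e.g. 10 electrodes).
#' @param coarseElectrodes normalized positions of the coarse subset.
#' @return list with \code{eag} ([EAGSnapshot-class] at the coarse
#'   positions), \code{csd} (coarse [CSDProfile-class]), \code{fineEAG},
#'   and the two models.
#' @examples
#' g <- speciesGeometry("Zcuc")
#' fm <- buildModel(g, seq(0, 1, length.out = 10))
#' rt <- runRoundtrip(makeTestCSD(2), fm, c(0, 1/3, 2/3, 1))
#' csdValues(rt$csd)  # reverse-polarity neighbors around a sub-compartment source
#' @export
runRoundtrip <- function(testCase, fineModel, coarseElectrodes) {
  csdFine <- if (is(testCase, "TestCase")) {
    if (testCase@kind != "fine")
      stop("strip cases (8-10) are handled by caseRatioReport()")
    testCase@values
  } else as.numeric(testCase)
  if (length(csdFine) != nCompartments(fineModel))
    stop("test profile length must equal the fine compartment count")
  finePos <- electrodePositions(fineModel)
  idx <- vapply(coarseElectrodes, function(p) {
    k <- which(abs(finePos - p) < 1e-9)
    if (length(k) != 1)
      stop("coarse electrode at ", p, " does not coincide with a fine position")
    k
  }, integer(1))
  phiFine <- predictEAG(fineModel, csdFine)
  coarseModel <- buildModel(modelGeometry(fineModel), coarseElectrodes,
                            lateralExtentMode(fineModel))
  phiCoarse <- new("EAGSnapshot", values = phiFine@values[idx],
                   positions = coarseElectrodes)
  list(eag = phiCoarse, csd = estimateCSD(coarseModel, phiCoarse),
       fineEAG = phiFine, fineModel = fineModel, coarseModel = coarseModel)
}

## predicted potentials of a strip case at the 4 electrodes of `model`
stripCasePotentials <- function(testCase, model) {
  g <- modelGeometry(model)
  L <- antennaLength(g)
  xe <- electrodePositions(model) * L
  ## lateral extent of the proximal compartment's source strip,
  ## scaled by the case's diameter factor (forward test model only)
  Y <- lateralHalfExtent(model)[1] * testCase@lateralScale
  stripPotential(xe, testCase@window[1] * L, testCase@window[2] * L,
                 Y, testCase@density, conductivity(g))
}

#' Quantitative bias ratios of the strip test cases
#'
#' Forward-projects cases 8, 9 and 10 on a 4-electrode model spanning the
#' funiculus, inverts the four potentials of each case with the same model,
#' and reports six ratios in percent of the case-8 value: the proximal and
#' second-electrode EAG and the proximal-compartment estimated CSD, for
#' case 9 and case 10.
#'
#' @param geometry an [AntennaGeometry-class] (default the Z. cucurbitae
#'   preset).
#' @param lateralExtentMode lateral bound convention (see [buildModel()]).
#' @param electrodes four regularly spaced normalized positions spanning
#'   the funiculus.
#' @return named numeric vector of the six ratios (percent), plus the raw
#'   potentials as attribute \code{"potentials"}.
#' @examples
#' caseRatioReport(speciesGeometry("Zcuc"), "half")
#' @export
caseRatioReport <- function(geometry = speciesGeometry("Zcuc"),
                            lateralExtentMode = c("printed", "half"),
                            electrodes = c(0, 1 / 3, 2 / 3, 1)) {
  lateralExtentMode <- match.arg(lateralExtentMode)
  model <- buildModel(geometry, electrodes, lateralExtentMode)
  Finv <- invertTransfer(transferMatrix(model))
  phi <- sapply(c(8, 9, 10), function(k)
    stripCasePotentials(makeTestCSD(k), model))
  colnames(phi) <- c("case8", "case9", "case10")
  csd <- Finv %*% phi
  dimnames(csd) <- dimnames(phi) <- list(NULL, c("case8", "case9", "case10"))
  out <- stats::setNames(
    100 * c(phi[1, "case9"] / phi[1, "case8"],
            phi[2, "case9"] / phi[2, "case8"],
            csd[1, "case9"] / csd[1, "case8"],
            phi[1, "case10"] / phi[1, "case8"],
            phi[2, "case10"] / phi[2, "case8"],
            csd[1, "case10"] / csd[1, "case8"]),
    c("case9_eagProximal", "case9_eagSecond", "case9_csdProximal",
      "case10_eagProximal", "case10_eagSecond", "case10_csdProximal"))
  attr(out, "potentials") <- phi
  out
}

#' Random-activation simulation of response densities
#'
#' Each simulation draws one activation level per basiconic sensilla class,
#' builds the resulting response-density curve, treats it as a current
#' source profile on a fine model (100 compartments by default), computes
#' the EAG at 4 electrode positions, estimates the CSD back with a
#' 4-compartment model, and averages the density over the 4 compartment
#' windows.  The pooled per-compartment points are then regressed (OLS) on
#' the response density, separately for the CSD and the EAG readouts; a
#' compartment-position factor model is also fitted.  The CSD is the
#' finer-grained linear readout, so its pooled r-squared exceeds the EAG's,
#' its zero-density intercept is slightly negative (compensatory reverse
#' polarity around sub-compartment structure) and the EAG's is positive
#' (distant sources contribute additively).
#'
#' @param nSims number of simulations (>= 2; default 1000).
#' @param seed RNG seed.
#' @param fineResolution number of fine compartments (default 100).
#' @param electrodes normalized positions of the recording subset; must lie
#'   on the fine electrode grid.
#' @param geometry antennal geometry (default the D. melanogaster preset).
#' @param classes sensilla classes; only basiconic classes are activated.
#' @param activation distribution of the activation levels,
#'   \code{"uniform"} on [0, 1] or \code{"exponential"} (rate 1).
#' @param lateralExtentMode lateral bound convention.
#' @param gridN resolution of the density evaluation grid used per class.
#' @return list with the pooled matrices (\code{density}, \code{eag},
#'   \code{csd}; nSims x 4), the two \code{lm} fits (\code{fitCSD},
#'   \code{fitEAG}), their r-squared / intercepts / F statistics, and the
#'   position-factor F statistics.
#' @export
randomActivationExperiment <- function(nSims = 1000, seed = 0,
                                       fineResolution = 100,
                                       electrodes = c(0, 1 / 3, 2 / 3, 1),
                                       geometry = speciesGeometry("Dmel"),
                                       classes = defaultSensillaClasses(),
                                       activation = c("uniform", "exponential"),
                                       lateralExtentMode = c("printed", "half"),
                                       gridN = 1000) {
  activation <- match.arg(activation)
  lateralExtentMode <- match.arg(lateralExtentMode)
  if (nSims < 2) stop("nSims must be at least 2")
  set.seed(seed)

  basic <- Filter(function(cl) cl@family == "basiconic", classes)
  fineModel <- buildModel(geometry, seq(0, 1, length.out = fineResolution),
                          lateralExtentMode)
  coarseModel <- buildModel(geometry, electrodes, lateralExtentMode)
  finePos <- electrodePositions(fineModel)
  idx <- vapply(electrodes, function(p) which.min(abs(finePos - p)), integer(1))
  if (max(abs(finePos[idx] - electrodes)) > 1e-9)
    stop("electrodes must lie on the fine model's electrode grid")

  ## per-class sensilla-density value at the fine compartment midpoints:
  ## one activation draw then weights this fixed basis
  mids <- compartmentMidpoints(fineModel)
  basis <- vapply(basic, function(cl) sensillaDensity(cl, mids),
                  numeric(length(mids)))

  Ffine <- transferMatrix(fineModel)@coefficients[idx, , drop = FALSE]
  Finv <- invertTransfer(transferMatrix(coarseModel))
  winC <- compartmentWindows(coarseModel) / antennaLength(geometry)
  memb <- findInterval(mids, c(winC[, 1], 1), rightmost.closed = TRUE)
  memb[memb > nrow(winC)] <- nrow(winC)

  nE <- length(electrodes)
  density <- eag <- csd <- matrix(0, nSims, nE)
  for (s in seq_len(nSims)) {
    act <- switch(activation,
                  uniform = stats::runif(length(basic)),
                  exponential = stats::rexp(length(basic)))
    curve <- as.vector(basis %*% act)
    phi <- as.vector(Ffine %*% curve)
    density[s, ] <- tapply(curve, memb, mean)
    eag[s, ] <- phi
    csd[s, ] <- as.vector(Finv %*% phi)
  }

  d <- as.vector(density)
  pos <- factor(rep(seq_len(nE), each = nSims))
  fitCSD <- stats::lm(as.vector(csd) ~ d)
  fitEAG <- stats::lm(as.vector(eag) ~ d)
  fitCSDpos <- stats::lm(as.vector(csd) ~ d + pos)
  fitEAGpos <- stats::lm(as.vector(eag) ~ d + pos)
  posF <- function(full, base) stats::anova(base, full)$F[2]
  list(density = density, eag = eag, csd = csd,
       fitCSD = fitCSD, fitEAG = fitEAG,
       r2CSD = summary(fitCSD)$r.squared,
       r2EAG = summary(fitEAG)$r.squared,
       interceptCSD = unname(stats::coef(fitCSD)[1]),
       interceptEAG = unname(stats::coef(fitEAG)[1]),
       fCSD = summary(fitCSD)$fstatistic[["value"]],
       fEAG = summary(fitEAG)$fstatistic[["value"]],
       posFCSD = posF(fitCSDpos, fitCSD),
       posFEAG = posF(fitEAGpos, fitEAG))
}

## default regularly interleaved index subsets of a 7-position array;
## size-3 comes with and without the extremities, size-2 in three variants
defaultSubsets <- function() {
  list(`7` = list(1:7), `4` = list(c(1L, 3L, 5L, 7L)),
       `3` = list(c(1L, 4L, 7L), c(2L, 4L, 6L)),
       `2` = list(c(1L, 7L), c(1L, 4L), c(4L, 7L)))
}

#' Re-estimate CSD maps from electrode subsets
#'
#' For each regularly interleaved subset of the recorded positions, builds
#' the matching coarse model (outer compartments extended to the arista and
#' the tip), estimates the CSD map, quantifies per-compartment response
#' areas and localizes the response by its center of mass.
#'
#' @param recording a preprocessed [EAGRecording-class] (typically 7
#'   channels) with at least one stimulus onset.
#' @param geometry antennal geometry.
#' @param subsetSizes sizes to analyse (subset of 2, 3, 4, 7).
#' @param subsets optional explicit list of index-vector lists per size
#'   (as [defaultSubsets()]).
#' @param lateralExtentMode lateral bound convention.
#' @return a list, one entry per subset variant, each with the index set,
#'   the model, the [CSDMap-class], per-compartment response \code{areas}
#'   and the \code{centerOfMass}.
#' @export
subsetAnalysis <- function(recording, geometry = speciesGeometry("Zcuc"),
                           subsetSizes = c(2, 3, 4, 7),
                           subsets = defaultSubsets(),
                           lateralExtentMode = c("printed", "half")) {
  lateralExtentMode <- match.arg(lateralExtentMode)
  if (!length(recording@onsets)) stop("recording has no stimulus onset")
  onset <- recording@onsets[1]
  out <- list()
  for (sz in as.character(subsetSizes)) {
    if (is.null(subsets[[sz]])) stop("no subset definition for size ", sz)
    for (idx in subsets[[sz]]) {
      if (any(idx > ncol(recording@traces)))
        stop("subset index outside the recorded positions")
      pos <- recording@positions[idx]
      model <- buildModel(geometry, pos, lateralExtentMode)
      sub <- eagRecording(recording@time, recording@traces[, idx, drop = FALSE],
                          recording@samplingRate, recording@onsets, pos)
      map <- estimateCSDTimeseries(model, sub)
      areas <- apply(map@values, 2, csdResponseArea, time = map@time,
                     onset = onset)
      out[[paste0("n", sz, "_", paste(idx, collapse = ""))]] <- list(
        indices = idx, model = model, map = map, areas = areas,
        centerOfMass = centerOfMass(areas, compartmentMidpoints(model)))
    }
  }
  out
}

#' Estimate the same EAG distribution under different geometries
#'
#' Rebuilds the model for each candidate geometry at the snapshot's
#' electrode positions and estimates the CSD.  The peak compartment is
#' robust to the modeled geometry; the amplitudes are not, and across cone
#' variants the per-compartment CSD level anticorrelates with the modeled
#' compartment surface area.
#'
#' @param snapshot an [EAGSnapshot-class].
#' @param geometries list of [AntennaGeometry-class] objects.
#' @param lateralExtentMode lateral bound convention.
#' @return list with the CSD matrix (geometries x compartments), the peak
#'   compartment per geometry (peak of the negative, sink, direction when
#'   sinks dominate, otherwise of the absolute response), the relative
#'   neighbor amplitudes and the compartment surface areas.
#' @export
geometrySweep <- function(snapshot, geometries,
                          lateralExtentMode = c("printed", "half")) {
  lateralExtentMode <- match.arg(lateralExtentMode)
  if (is.null(names(geometries)))
    names(geometries) <- vapply(geometries, function(g) g@species, character(1))
  n <- length(snapshot@values)
  csd <- matrix(0, length(geometries), n,
                dimnames = list(names(geometries), NULL))
  surface <- csd
  for (k in seq_along(geometries)) {
    model <- buildModel(geometries[[k]], snapshot@positions, lateralExtentMode)
    csd[k, ] <- csdValues(estimateCSD(model, snapshot))
    w <- compartmentWindows(model)
    surface[k, ] <- (w[, 2] - w[, 1]) * compartmentCircumferences(model)
  }
  peak <- apply(csd, 1, function(v) which.max(abs(v)))
  relNeighbor <- t(apply(csd, 1, function(v) v / v[which.max(abs(v))]))
  list(csd = csd, peakCompartment = peak, relativeToPeak = relNeighbor,
       compartmentSurface = surface)
}

#' Synthesize an EAG recording from a space-time CSD profile
#'
#' Forward-projects each time point of a CSD profile through the model's
#' transfer matrix and adds i.i.d. Gaussian noise, producing a fixture
#' recording with full metadata.  Deterministic for a fixed seed.
#'
#' @param model a [CompartmentModel-class].
#' @param csdTime nTime x nCompartments matrix of CSD values (sinks
#'   negative), or a [CSDMap-class].
#' @param samplingRate sampling rate (Hz, default 500).
#' @param onset stimulus onset (s) stamped into the metadata.
#' @param noiseSd standard deviation of the additive Gaussian noise (mV).
#' @param seed RNG seed.
#' @param t0 time of the first sample (s).
#' @return an [EAGRecording-class].
#' @export
synthesizeRecording <- function(model, csdTime, samplingRate = 500,
                                onset = 0, noiseSd = 0, seed = 0, t0 = NULL) {
  if (is(csdTime, "CSDMap")) csdTime <- csdTime@values
  csdTime <- as.matrix(csdTime)
  if (ncol(csdTime) != nCompartments(model))
    stop("csdTime must have one column per model compartment")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  tm <- transferMatrix(model)
  phi <- t(tm@coefficients %*% t(csdTime))
  if (noiseSd > 0) {
    set.seed(seed)
    phi <- phi + matrix(stats::rnorm(length(phi), sd = noiseSd),
                        nrow(phi), ncol(phi))
  }
  if (is.null(t0)) t0 <- onset - 1
  time <- t0 + (seq_len(nrow(phi)) - 1) / samplingRate
  eagRecording(time, phi, samplingRate, onsets = onset,
               positions = electrodePositions(model))
}
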