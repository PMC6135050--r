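#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Physical description of an insect antenna (funiculus)
#'
#' An \code{AntennaGeometry} holds the measured dimensions of the third
#' antennal segment together with the electrical assumptions of the surface
#' conduction model.  Lengths are in mm.  The cross-section is an ellipse
#' with axes \code{width} and \code{thickness}; a \code{"cone"} shape tapers
#' the diameter linearly along the proximo-distal axis while keeping the
#' average diameter equal to \code{width} (so cone variants are directly
#' comparable to the cylinder of the same nominal size).
#'
#' @slot species species label, e.g. \code{"Zcuc"}.
#' @slot length funiculus length (mm).
#' @slot width funiculus width (mm); for a cone this is the average diameter.
#' @slot thickness funiculus thickness (mm).
#' @slot shape \code{"cylinder"} or \code{"cone"}.
#' @slot taperRatio distal diameter / proximal diameter (1 for a cylinder).
#' @slot sigma surface conductivity scalar (default 10, the median measured
#'   value); acts as a pure prefactor on all potentials and CSD amplitudes.
#'
#' @seealso [antennaGeometry()], [speciesPresets()], [buildModel()]
#' @export
setClass("AntennaGeometry", representation(
  species = "character", length = "numeric", width = "numeric",
  thickness = "numeric", shape = "character", taperRatio = "numeric",
  sigma = "numeric"
))

setValidity("AntennaGeometry", function(object) {
  msg <- character()
  if (length(object@length) != 1 || !is.finite(object@length) || object@length <= 0)
    msg <- c(msg, "length must be a single positive number")
  if (length(object@width) != 1 || !is.finite(object@width) || object@width <= 0)
    msg <- c(msg, "width must be a single positive number")
  if (length(object@thickness) != 1 || !is.finite(object@thickness) || object@thickness <= 0)
    msg <- c(msg, "thickness must be a single positive number")
  if (!object@shape %in% c("cylinder", "cone"))
    msg <- c(msg, "shape must be 'cylinder' or 'cone'")
  if (object@shape == "cylinder" && !isTRUE(all.equal(object@taperRatio, 1)))
    msg <- c(msg, "cylinder implies taperRatio = 1")
  if (object@shape == "cone" &&
      (object@taperRatio <= 0 || isTRUE(all.equal(object@taperRatio, 1))))
    msg <- c(msg, "cone requires taperRatio > 0 and != 1")
  if (length(object@sigma) != 1 || !is.finite(object@sigma) || object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Electrode positions along the proximo-distal axis
#'
#' Positions are normalized to [0, 1]: 0 is the base of the arista
#' (most proximal olfactory sensilla), 1 the tip of the funiculus.
#' At least two strictly increasing positions are required.  Regularly
#' interleaved arrays are the common case but irregular spacings are
#' supported; compartment boundaries are then placed at gap midpoints.
#'
#' @slot positions numeric vector of normalized positions.
#' @seealso [electrodeArray()], [buildModel()]
#' @export
setClass("ElectrodeArray", representation(positions = "numeric"))

setValidity("ElectrodeArray", function(object) {
  p <- object@positions
  if (length(p) < 2) return("at least 2 electrode positions are required")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    return("electrode positions must be finite and inside [0, 1]")
  if (any(diff(p) <= 0)) return("electrode positions must be strictly increasing")
  TRUE
})

#' Compartmentalized antenna model
#'
#' Discretization of the antennal surface into one compartment per electrode:
#' proximo-distal integration windows (mm), per-compartment cross-section
#' circumferences (mm) and the lateral extent convention used in the forward
#' integral.  Built by [buildModel()].
#'
#' @slot geometry an [AntennaGeometry-class].
#' @slot electrodes an [ElectrodeArray-class].
#' @slot windows N x 2 matrix of compartment intervals \code{[lo, hi]} in mm.
#' @slot circumferences per-compartment circumference q (mm), evaluated at
#'   the compartment midpoint for cones.
#' @slot lateralExtentMode \code{"printed"} (lateral bounds -q..q, the
#'   formula as printed) or \code{"half"} (-q/2..q/2, the physically
#'   consistent unfolding of the surface).
#' @export
setClass("CompartmentModel", representation(
  geometry = "AntennaGeometry", electrodes = "ElectrodeArray",
  windows = "matrix", circumferences = "numeric",
  lateralExtentMode = "character"
))

setValidity("CompartmentModel", function(object) {
  w <- object@windows
  n <- length(object@electrodes@positions)
  msg <- character()
  if (nrow(w) != n || ncol(w) != 2)
    msg <- c(msg, "windows must be an N x 2 matrix matching the electrode count")
  if (any(w[, 2] <= w[, 1])) msg <- c(msg, "each window must have hi > lo")
  L <- object@geometry@length
  if (abs(sum(w[, 2] - w[, 1]) - L) > 1e-9 * L)
    msg <- c(msg, "windows must cover the full funiculus length")
  if (nrow(w) > 1 && any(abs(w[-nrow(w), 2] - w[-1, 1]) > 1e-9 * L))
    msg <- c(msg, "windows must be contiguous")
  if (length(object@circumferences) != n || any(object@circumferences <= 0))
    msg <- c(msg, "need one positive circumference per compartment")
  if (!object@lateralExtentMode %in% c("printed", "half"))
    msg <- c(msg, "lateralExtentMode must be 'printed' or 'half'")
  if (length(msg)) msg else TRUE
})

#' Transfer matrix from compartmental CSD to electrode potentials
#'
#' Entry \code{[i, j]} is the potential at electrode i per unit current
#' source density in compartment j.  All entries are positive and each row
#' peaks at the compartment containing its electrode.
#'
#' @slot coefficients N x N numeric matrix.
#' @slot model the [CompartmentModel-class] the coefficients were computed for.
#' @seealso [transferMatrix()], [invertTransfer()]
#' @export
setClass("TransferMatrix", representation(
  coefficients = "matrix", model = "CompartmentModel"
))

#' Single-time-point EAG distribution
#'
#' @slot values potential per electrode (mV).
#' @slot positions normalized electrode positions.
#' @export
setClass("EAGSnapshot", representation(values = "numeric", positions = "numeric"))

setValidity("EAGSnapshot", function(object) {
  if (length(object@values) != length(object@positions))
    return("values and positions must have equal length")
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' Per-compartment current source density profile
#'
#' Negative values are current sinks (sites of ORN activation; they induce
#' negative EAG potentials), positive values are return current sources.
#'
#' @slot values CSD per compartment.
#' @slot model the [CompartmentModel-class] defining the compartments.
#' @export
setClass("CSDProfile", representation(values = "numeric", model = "CompartmentModel"))

setValidity("CSDProfile", function(object) {
  if (length(object@values) != nrow(object@model@windows))
    return("values length must equal the compartment count")
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' Multi-channel EAG recording
#'
#' Time series of antennal potentials, one column per electrode, with
#' stimulus metadata and an optional paired control recording (same
#' time base) used for control subtraction.
#'
#' @slot time time axis in s.
#' @slot traces nTime x nElectrodes matrix (mV).
#' @slot samplingRate sampling rate in Hz (500 by default in this field).
#' @slot onsets stimulus onset times (s).
#' @slot positions normalized electrode positions.
#' @slot control optional control traces, same dimensions as \code{traces}.
#' @seealso [eagRecording()], [preprocessEAG()], [estimateCSDTimeseries()]
#' @export
setClass("EAGRecording", representation(
  time = "numeric", traces = "matrix", samplingRate = "numeric",
  onsets = "numeric", positions = "numeric", control = "matrixOrNULL"
))

setValidity("EAGRecording", function(object) {
  msg <- character()
  if (nrow(object@traces) != length(object@time))
    msg <- c(msg, "traces must have one row per time sample")
  if (ncol(object@traces) != length(object@positions))
    msg <- c(msg, "traces must have one column per electrode position")
  if (length(object@time) > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (!is.null(object@control) && !identical(dim(object@control), dim(object@traces)))
    msg <- c(msg, "control must have the same dimensions as traces")
  if (length(msg)) msg else TRUE
})

#' Space-time CSD map
#'
#' CSD estimated at each time point, one column per compartment.
#'
#' @slot time time axis in s (uniformly sampled, strictly increasing).
#' @slot values nTime x nCompartments matrix.
#' @slot model the [CompartmentModel-class] used for the estimate.
#' @export
setClass("CSDMap", representation(
  time = "numeric", values = "matrix", model = "CompartmentModel"
))

setValidity("CSDMap", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@time))
    msg <- c(msg, "values must have one row per time sample")
  if (ncol(object@values) != nrow(object@model@windows))
    msg <- c(msg, "values must have one column per compartment")
  if (length(object@time) > 1) {
    dt <- diff(object@time)
    if (any(dt <= 0)) msg <- c(msg, "time must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
      msg <- c(msg, "time must be uniformly sampled")
  }
  if (length(msg)) msg else TRUE
})

#' A named sensilla class on the Drosophila antenna
#'
#' @slot name class label (ab1..ab10 basiconic, at1..at4 trichoid).
#' @slot count sensilla per antenna (fractional counts allowed, they are
#'   averages over individuals).
#' @slot center center of the logit-normal spatial distribution (normalized).
#' @slot sd spatial standard deviation in position units.
#' @slot family \code{"basiconic"} or \code{"trichoid"}.
#' @slot responses per-ORN response levels (consensual scaled units);
#'   zero-length means no response data.
#' @seealso [sensillaClass()], [defaultSensillaClasses()]
#' @export
setClass("SensillaClass", representation(
  name = "character", count = "numeric", center = "numeric",
  sd = "numeric", family = "character", responses = "numeric"
))

setValidity("SensillaClass", function(object) {
  msg <- character()
  if (object@count <= 0) msg <- c(msg, "count must be positive")
  if (object@center <= 0 || object@center >= 1)
    msg <- c(msg, "center must be inside (0, 1)")
  if (object@sd <= 0) msg <- c(msg, "sd must be positive")
  if (!object@family %in% c("basiconic", "trichoid"))
    msg <- c(msg, "family must be 'basiconic' or 'trichoid'")
  if (length(msg)) msg else TRUE
})

#' Response density along the antenna
#'
#' Sum over sensilla classes of (summed ORN responses) x (sensilla count) x
#' (spatial density), evaluated on a uniform grid over (0, 1).  Units are
#' response per unit antennal length.
#'
#' @slot grid evaluation grid (normalized positions, uniform).
#' @slot density density values on the grid.
#' @export
setClass("ResponseDensityCurve", representation(grid = "numeric", density = "numeric"))

setValidity("ResponseDensityCurve", function(object) {
  if (length(object@grid) != length(object@density))
    return("grid and density must have equal length")
  if (length(object@grid) > 2) {
    dg <- diff(object@grid)
    if (max(dg) - min(dg) > 1e-8 * mean(dg)) return("grid must be uniform")
  }
  TRUE
})

#' Artificial CSD test distribution
#'
#' Test distributions used to characterize estimation biases.  Cases 1-7 are
#' 0/1 profiles on a 10-compartment fine model; cases 8-10 are rectangular
#' strips on the proximal compartment of a 4-compartment model (case 9 halves
#' the proximo-distal window, case 10 halves the source-strip diameter, both
#' doubling the density so total current is conserved).
#'
#' @slot caseId integer 1..10.
#' @slot kind \code{"fine"} (10-bin profile) or \code{"strip"}.
#' @slot values the 10-bin profile (fine cases) or empty.
#' @slot window normalized proximo-distal extent of the strip (strip cases).
#' @slot density source density on the strip.
#' @slot lateralScale multiplier on the source-strip diameter (1 or 0.5).
#' @slot description human-readable summary.
#' @seealso [makeTestCSD()], [runRoundtrip()], [caseRatioReport()]
#' @export
setClass("TestCase", representation(
  caseId = "integer", kind = "character", values = "numeric",
  window = "numeric", density = "numeric", lateralScale = "numeric",
  description = "character"
))
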