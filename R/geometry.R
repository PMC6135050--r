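#' Create an antenna geometry
#'
#' @param species species label.
#' @param length,width,thickness funiculus dimensions in mm.  \code{width}
#'   should not exceed \code{length} (a warning, not an error: some
#'   filamentous antennae are borderline and users may pass partial segments).
#' @param shape \code{"cylinder"} (default) or \code{"cone"}.
#' @param taperRatio distal diameter / proximal diameter; must be 1 for a
#'   cylinder and a positive value different from 1 for a cone.
#' @param sigma surface conductivity scalar (default 10, the median measured
#'   across individuals).  It scales all potentials and estimated CSD values
#'   multiplicatively and has no effect on their spatial distribution.
#' @return an [AntennaGeometry-class] object.
#' @examples
#' antennaGeometry("Zcuc", length = 1.0, width = 0.30, thickness = 0.30)
#' @export
antennaGeometry <- function(species = "custom", length, width,
                            thickness = width, shape = c("cylinder", "cone"),
                            taperRatio = 1, sigma = 10) {
  shape <- match.arg(shape)
  if (any(c(length, width, thickness) < 0, na.rm = TRUE))
    stop("antenna dimensions must be positive")
  g <- new("AntennaGeometry", species = species, length = length,
           width = width, thickness = thickness, shape = shape,
           taperRatio = taperRatio, sigma = sigma)
  if (width > length)
    warning("width exceeds length; check the units (both are in mm)")
  g
}

#' @rdname antennaGeometry
#' @param object,x an \code{AntennaGeometry}.
#' @export
antennaLength <- function(x) x@length

#' @rdname antennaGeometry
#' @export
antennaWidth <- function(x) x@width

#' @rdname antennaGeometry
#' @export
antennaThickness <- function(x) x@thickness

#' @rdname antennaGeometry
#' @export
antennaShape <- function(x) x@shape

#' @rdname antennaGeometry
#' @export
conductivity <- function(x) x@sigma

setMethod("show", "AntennaGeometry", function(object) {
  cat(sprintf("AntennaGeometry '%s': %s, length %.3g mm, width %.3g mm, thickness %.3g mm",
              object@species, object@shape, object@length, object@width,
              object@thickness))
  if (object@shape == "cone") cat(sprintf(", taper %.3g", object@taperRatio))
  cat(sprintf(", sigma %.3g\n", object@sigma))
})

#' Create an electrode array
#'
#' @param positions strictly increasing normalized positions in [0, 1]
#'   (0 = base of the arista, 1 = funiculus tip); at least 2.
#' @return an [ElectrodeArray-class].
#' @examples
#' electrodeArray(c(0, 1/3, 2/3, 1))
#' @export
electrodeArray <- function(positions) new("ElectrodeArray", positions = positions)

#' @rdname electrodeArray
#' @param x an \code{ElectrodeArray} or \code{CompartmentModel}.
#' @export
electrodePositions <- function(x) {
  if (is(x, "CompartmentModel")) x@electrodes@positions else x@positions
}

setMethod("show", "ElectrodeArray", function(object) {
  cat("ElectrodeArray with", length(object@positions), "positions:",
      paste(signif(object@positions, 4), collapse = ", "), "\n")
})

#' Ramanujan approximation of an ellipse circumference
#'
#' \code{pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))}, exact for a
#' circle and within 0.05 percent of the true arc length for the aspect
#' ratios encountered in antennal cross-sections.
#'
#' @param a,b the two semi-axes (mm); non-negative, not both zero.
#' @return the circumference in mm.
#' @examples
#' ellipseCircumference(0.15, 0.15)  # 2 * pi * 0.15
#' @export
ellipseCircumference <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("semi-axes must be non-negative")
  if (any(a == 0 & b == 0)) stop("semi-axes must not both be zero")
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

## Diameter scale factor along the axis (1 for cylinders).  For cones the
## diameter varies linearly with the average kept at the nominal width:
## proximal scale 2/(1+t), distal scale 2t/(1+t) with t = taperRatio.
diameterScale <- function(geometry, xNorm) {
  if (geometry@shape == "cylinder") return(rep(1, length(xNorm)))
  t <- geometry@taperRatio
  sProx <- 2 / (1 + t)
  sProx + (t * sProx - sProx) * xNorm
}

#' Build a compartmentalized antenna model
#'
#' One compartment per electrode.  Interior compartment boundaries sit at
#' the midpoints between neighboring electrodes; the outer compartments are
#' extended to the arista (0) and to the funiculus tip (length), which for
#' electrodes placed at the extremities reduces to the half-width edge
#' windows \code{[x1, x1 + h/2]} and \code{[xN - h/2, xN]}.  Compartment
#' circumferences come from the Ramanujan formula; for cones the
#' cross-section is evaluated at the compartment midpoint.
#'
#' @param geometry an [AntennaGeometry-class].
#' @param electrodes an [ElectrodeArray-class] or a numeric vector of
#'   normalized positions.
#' @param lateralExtentMode lateral integration bounds of the forward model:
#'   \code{"printed"} uses -q..q with q the full circumference (the formula
#'   as printed), \code{"half"} uses -q/2..q/2 (the exact unfolding of the
#'   surface).  The two differ by a smooth rescaling of the coefficient
#'   profiles.
#' @return a [CompartmentModel-class].
#' @examples
#' g <- speciesGeometry("Zcuc")
#' buildModel(g, c(0, 1/3, 2/3, 1))
#' @export
buildModel <- function(geometry, electrodes,
                       lateralExtentMode = c("printed", "half")) {
  lateralExtentMode <- match.arg(lateralExtentMode)
  if (is.numeric(electrodes)) electrodes <- electrodeArray(electrodes)
  L <- geometry@length
  xe <- electrodes@positions * L
  n <- length(xe)
  cuts <- c(0, (xe[-n] + xe[-1]) / 2, L)
  windows <- cbind(lo = cuts[-(n + 1)], hi = cuts[-1])
  mid <- (windows[, 1] + windows[, 2]) / 2 / L
  s <- diameterScale(geometry, mid)
  q <- ellipseCircumference(geometry@width / 2 * s, geometry@thickness / 2 * s)
  new("CompartmentModel", geometry = geometry, electrodes = electrodes,
      windows = windows, circumferences = q,
      lateralExtentMode = lateralExtentMode)
}

#' @rdname buildModel
#' @param model a \code{CompartmentModel}.
#' @export
nCompartments <- function(model) nrow(model@windows)

#' @rdname buildModel
#' @export
compartmentWindows <- function(model) model@windows

#' @rdname buildModel
#' @export
compartmentCircumferences <- function(model) model@circumferences

#' @rdname buildModel
#' @details \code{compartmentMidpoints} returns normalized midpoints, the
#'   positions used for center-of-mass localization and map headers.
#' @export
compartmentMidpoints <- function(model) {
  (model@windows[, 1] + model@windows[, 2]) / 2 / model@geometry@length
}

#' @rdname buildModel
#' @export
lateralExtentMode <- function(model) model@lateralExtentMode

#' @rdname buildModel
#' @export
modelGeometry <- function(model) model@geometry

## lateral half-extent of the source rectangle per compartment (mm)
lateralHalfExtent <- function(model) {
  if (model@lateralExtentMode == "printed") model@circumferences
  else model@circumferences / 2
}

setMethod("show", "CompartmentModel", function(object) {
  cat(sprintf("CompartmentModel (%s, %s lateral bounds): %d compartments on '%s'\n",
              object@geometry@shape, object@lateralExtentMode,
              nrow(object@windows), object@geometry@species))
  w <- signif(object@windows, 4)
  cat("  windows (mm):", paste(sprintf("[%g, %g]", w[, 1], w[, 2]), collapse = " "), "\n")
  cat("  circumferences (mm):", paste(signif(object@circumferences, 4), collapse = ", "), "\n")
})

## ---- species presets -------------------------------------------------------

## Fly dimensions are representative values inside the measured ranges
## (funiculus length 0.15-1.1 mm, width/length 0.2-0.6; the larger antennae
## tend to be the more elongated).  The moth preset uses the measured
## 13 mm x 0.125 mm.  Thickness defaults to width (near-circular sections).
presetTable <- function() {
  data.frame(
    species = c("Dmel", "Ccap", "Ccat", "Ncya", "Bzon", "Zcuc", "Ddem", "Csac"),
    length = c(0.15, 0.35, 0.40, 0.55, 1.05, 1.00, 1.10, 13),
    width = c(0.090, 0.190, 0.200, 0.250, 0.420, 0.300, 0.275, 0.125),
    stringsAsFactors = FALSE
  )
}

#' Species presets for antennal geometries
#'
#' Named geometry presets for seven fly species (Drosophila melanogaster
#' \code{Dmel}, Ceratitis capitata \code{Ccap}, C. catoirii \code{Ccat},
#' Neoceratitis cyanescens \code{Ncya}, Bactrocera zonata \code{Bzon},
#' Zeugodacus cucurbitae \code{Zcuc}, Dacus demmerezi \code{Ddem}) and the
#' moth Chilo sacchariphagus (\code{Csac}).  Fly dimensions are
#' representative values within the measured ranges and are meant to be
#' edited against one's own microscope measurements; quantitative work
#' should always state the geometry used.  \code{Zcuc} is the package-wide
#' default geometry.
#'
#' @return \code{speciesPresets()}: a named list of
#'   [AntennaGeometry-class] objects.
#' @examples
#' names(speciesPresets())
#' speciesGeometry("Csac")
#' @export
speciesPresets <- function() {
  tab <- presetTable()
  out <- lapply(seq_len(nrow(tab)), function(i)
    antennaGeometry(tab$species[i], length = tab$length[i],
                    width = tab$width[i], thickness = tab$width[i]))
  names(out) <- tab$species
  out
}

#' @rdname speciesPresets
#' @param species one of the preset labels.
#' @return \code{speciesGeometry()}: a single [AntennaGeometry-class].
#' @export
speciesGeometry <- function(species = "Zcuc") {
  presets <- speciesPresets()
  if (!species %in% names(presets))
    stop("unknown species '", species, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[species]]
}
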