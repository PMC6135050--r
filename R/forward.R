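## Electrostatic forward solution on the unfolded antennal surface.
##
## A uniform rectangular current source produces, at a point in its plane, a
## potential proportional to the integral of 1/r over the rectangle.  With
## the electrode at the origin, the integral over [x1,x2] x [y1,y2] has the
## closed form assembled from the corner primitive
##   G(a, b) = a*asinh(b/a) + b*asinh(a/b) = int_0^a int_0^b dx dy / r,
## combined with signs so that the 1/r singularity (electrode inside the
## rectangle) is handled exactly.

cornerIntegral <- function(a, b) {
  out <- numeric(length(a))
  ok <- a != 0 & b != 0
  out[ok] <- a[ok] * asinh(b[ok] / a[ok]) + b[ok] * asinh(a[ok] / b[ok])
  out
}

signedCorner <- function(a, b) sign(a) * sign(b) * cornerIntegral(abs(a), abs(b))

## integral of 1/sqrt(x^2 + y^2) over [x1,x2] x [y1,y2]
rectKernelIntegral <- function(x1, x2, y1, y2) {
  signedCorner(x2, y2) - signedCorner(x1, y2) -
    signedCorner(x2, y1) + signedCorner(x1, y1)
}

## same integral by semi-analytic quadrature (inner x-integral analytic,
## outer y-integral numeric, split at y = 0 where the integrand has its
## integrable log singularity).  Kept as an in-package alternative route;
## the test suite uses fully independent oracles.
rectKernelQuadrature <- function(x1, x2, y1, y2, tol = 1e-10) {
  inner <- function(y) asinh(x2 / abs(y)) - asinh(x1 / abs(y))
  piece <- function(lo, hi) {
    if (hi <= lo) return(0)
    stats::integrate(inner, lo, hi, rel.tol = tol, abs.tol = tol,
                     subdivisions = 500L)$value
  }
  if (y1 >= 0 || y2 <= 0) piece(min(abs(c(y1, y2))), max(abs(c(y1, y2))))
  else piece(0, -y1) + piece(0, y2)
}

## potential (per 1/(4*pi*sigma)) of a strip [lo,hi] x [-Y,Y] at electrode
## positions xe (all in mm), times density
stripPotential <- function(xe, lo, hi, Y, density = 1, sigma = 10) {
  vapply(xe, function(x)
    density * rectKernelIntegral(lo - x, hi - x, -Y, Y), numeric(1)) /
    (4 * pi * sigma)
}

#' Transfer coefficient between one compartment and one electrode
#'
#' The potential generated at electrode \code{i} by a unit current source
#' density spread uniformly over the rectangle of compartment \code{j}:
#' \deqn{F_{ij} = \frac{1}{4\pi\sigma}\int\!\!\int_{rect_j}
#'   \frac{dx\,dy}{\sqrt{(x - x_i)^2 + y^2}}}
#' with the proximo-distal window of compartment j and lateral bounds set by
#' the model's \code{lateralExtentMode}.  The integrable singularity when the
#' electrode lies inside the source rectangle is handled by the closed-form
#' antiderivative (default) or by singularity-splitting quadrature.
#'
#' @param model a [CompartmentModel-class].
#' @param i electrode index.
#' @param j compartment index.
#' @param method \code{"closed"} (exact antiderivative) or
#'   \code{"quadrature"} (semi-analytic adaptive quadrature).
#' @return the coefficient (potential per unit CSD).
#' @seealso [transferMatrix()]
#' @export
transferCoefficient <- function(model, i, j, method = c("closed", "quadrature")) {
  method <- match.arg(method)
  n <- nCompartments(model)
  if (i < 1 || i > n || j < 1 || j > n) stop("electrode/compartment index out of range")
  w <- model@windows
  if (w[j, 2] <= w[j, 1]) stop("compartment window has zero area")
  sigma <- model@geometry@sigma
  if (sigma <= 0) stop("sigma must be positive")
  xe <- model@electrodes@positions[i] * model@geometry@length
  Y <- lateralHalfExtent(model)[j]
  x1 <- unname(w[j, 1] - xe); x2 <- unname(w[j, 2] - xe)
  v <- switch(method,
    closed = rectKernelIntegral(x1, x2, -Y, Y),
    quadrature = rectKernelQuadrature(x1, x2, -Y, Y))
  v / (4 * pi * sigma)
}

#' Transfer matrix of a compartment model
#'
#' Assembles [transferCoefficient()] over all electrode/compartment pairs.
#' All entries are positive and decrease with electrode-compartment
#' distance, so each row peaks at its own compartment.
#'
#' @param model a [CompartmentModel-class].
#' @return a [TransferMatrix-class].
#' @examples
#' m <- buildModel(speciesGeometry("Zcuc"), c(0, 1/3, 2/3, 1))
#' transferMatrix(m)
#' @export
transferMatrix <- function(model) {
  n <- nCompartments(model)
  Fm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    Fm[i, j] <- transferCoefficient(model, i, j)
  new("TransferMatrix", coefficients = Fm, model = model)
}

#' @rdname transferMatrix
#' @param x a \code{TransferMatrix}.
#' @export
transferCoefficients <- function(x) x@coefficients

setMethod("show", "TransferMatrix", function(object) {
  cat(sprintf("TransferMatrix %d x %d ('%s', %s lateral bounds)\n",
              nrow(object@coefficients), ncol(object@coefficients),
              object@model@geometry@species, object@model@lateralExtentMode))
  print(signif(object@coefficients, 4))
})

#' Predict an EAG distribution from a CSD profile
#'
#' The linear forward map \code{phi = F C}: each compartment contributes
#' additively to every electrode potential.
#'
#' @param model a [CompartmentModel-class].
#' @param csd a numeric vector (one value per compartment) or a
#'   [CSDProfile-class].
#' @param tm optionally a precomputed [TransferMatrix-class] for
#'   \code{model}.
#' @return an [EAGSnapshot-class].
#' @export
predictEAG <- function(model, csd, tm = NULL) {
  if (is(csd, "CSDProfile")) csd <- csd@values
  if (length(csd) != nCompartments(model))
    stop("csd length (", length(csd), ") must equal the compartment count (",
         nCompartments(model), ")")
  if (is.null(tm)) tm <- transferMatrix(model)
  new("EAGSnapshot", values = as.vector(tm@coefficients %*% csd),
      positions = model@electrodes@positions)
}

#' @rdname predictEAG
#' @param x an \code{EAGSnapshot} or \code{CSDProfile}.
#' @export
snapshotValues <- function(x) x@values

setMethod("show", "EAGSnapshot", function(object) {
  cat("EAGSnapshot (mV) at", length(object@values), "positions:\n")
  print(signif(stats::setNames(object@values, signif(object@positions, 3)), 4))
})
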