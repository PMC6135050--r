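#' Invert a transfer matrix
#'
#' The CSD estimate is the exact linear inverse of the forward map
#' (\code{C = F^-1 phi}); no regularization is applied by default, matching
#' the well-conditioned N <= 7 regime of multi-position EAG arrays.  A
#' condition-number diagnostic is attached to the result; an error is raised
#' when it exceeds \code{condThreshold}.  A small ridge is available for
#' pathological irregular arrays.
#'
#' @param tm a [TransferMatrix-class] (or a plain square matrix).
#' @param condThreshold condition-number limit (default 1e6).
#' @param ridge optional Tikhonov ridge added as \code{ridge * mean(diag(F))}
#'   to the diagonal (default 0 = exact inversion).
#' @return the inverse matrix, with attribute \code{"conditionNumber"}.
#' @examples
#' m <- buildModel(speciesGeometry("Zcuc"), c(0, 1/3, 2/3, 1))
#' Fi <- invertTransfer(transferMatrix(m))
#' attr(Fi, "conditionNumber")
#' @export
invertTransfer <- function(tm, condThreshold = 1e6, ridge = 0) {
  Fm <- if (is(tm, "TransferMatrix")) tm@coefficients else tm
  if (!is.matrix(Fm) || nrow(Fm) != ncol(Fm))
    stop("the transfer matrix must be square (N electrodes = N compartments)")
  if (any(!is.finite(Fm))) stop("the transfer matrix must be finite")
  if (ridge > 0) Fm <- Fm + diag(ridge * mean(diag(Fm)), nrow(Fm))
  kap <- kappa(Fm, exact = TRUE)
  if (kap > condThreshold)
    stop(sprintf("transfer matrix is near-singular: condition number %.3g exceeds the threshold %.3g",
                 kap, condThreshold))
  Fi <- solve(Fm)
  attr(Fi, "conditionNumber") <- kap
  Fi
}

#' Estimate the CSD from a single EAG distribution
#'
#' Applies the inverse transfer matrix to one spatial distribution of EAG
#' potentials: \code{C_i = sum_j Finv_ij phi_j}.  Negative estimates are
#' current sinks (ORN activation).
#'
#' @param model a [CompartmentModel-class].
#' @param snapshot an [EAGSnapshot-class] or numeric vector (one potential
#'   per compartment/electrode).
#' @param Finv optionally a precomputed inverse from [invertTransfer()].
#' @return a [CSDProfile-class].
#' @examples
#' m <- buildModel(speciesGeometry("Zcuc"), c(0, 1/3, 2/3, 1))
#' phi <- predictEAG(m, c(-1, 0, 0, 0))
#' estimateCSD(m, phi)  # recovers (-1, 0, 0, 0)
#' @export
estimateCSD <- function(model, snapshot, Finv = NULL) {
  phi <- if (is(snapshot, "EAGSnapshot")) snapshot@values else snapshot
  if (length(phi) != nCompartments(model))
    stop("snapshot length (", length(phi),
         ") must equal the compartment count (", nCompartments(model), ")")
  if (is.null(Finv)) Finv <- invertTransfer(transferMatrix(model))
  new("CSDProfile", values = as.vector(Finv %*% phi), model = model)
}

#' @rdname estimateCSD
#' @param x a \code{CSDProfile}.
#' @export
csdValues <- function(x) x@values

setMethod("show", "CSDProfile", function(object) {
  cat("CSDProfile over", length(object@values), "compartments (sinks negative):\n")
  print(signif(stats::setNames(object@values,
                               signif(compartmentMidpoints(object@model), 3)), 4))
})

#' Estimate the CSD at every time point of a recording
#'
#' Column-wise application of [estimateCSD()]; the inverse is computed once.
#'
#' @param model a [CompartmentModel-class]; its compartment count must match
#'   the recording channel count.
#' @param recording an [EAGRecording-class].
#' @return a [CSDMap-class] sharing the recording's time axis.
#' @export
estimateCSDTimeseries <- function(model, recording) {
  if (ncol(recording@traces) != nCompartments(model))
    stop("recording has ", ncol(recording@traces),
         " channels but the model has ", nCompartments(model), " compartments")
  Finv <- invertTransfer(transferMatrix(model))
  vals <- t(Finv %*% t(recording@traces))
  new("CSDMap", time = recording@time, values = vals, model = model)
}

#' @rdname estimateCSDTimeseries
#' @param x a \code{CSDMap}.
#' @export
csdMapValues <- function(x) x@values

#' @rdname estimateCSDTimeseries
#' @export
csdMapTime <- function(x) x@time

setMethod("show", "CSDMap", function(object) {
  cat(sprintf("CSDMap: %d time points x %d compartments, t in [%.3g, %.3g] s\n",
              nrow(object@values), ncol(object@values),
              min(object@time), max(object@time)))
})

#' Classical second-difference CSD estimate
#'
#' The traditional approximation of the CSD by the negative second spatial
#' difference of the potential: interior positions get
#' \code{-0.5 phi[i-1] + phi[i] - 0.5 phi[i+1]}; the two end positions are
#' undefined (returned as NA), the classical limitation that the full
#' geometric inverse removes.  Requires a regularly spaced array.
#'
#' @param snapshot an [EAGSnapshot-class] or numeric vector (length >= 3).
#' @param positions electrode positions (needed to check spacing when
#'   \code{snapshot} is a bare vector; defaults to a regular grid).
#' @return numeric vector of length N with NA at the endpoints.
#' @examples
#' classicalCSD(c(0, 1, 0, 0))  # NA, 1, -0.5, NA
#' @export
classicalCSD <- function(snapshot, positions = NULL) {
  if (is(snapshot, "EAGSnapshot")) {
    positions <- snapshot@positions
    snapshot <- snapshot@values
  }
  n <- length(snapshot)
  if (n < 3) stop("at least 3 positions are required")
  if (is.null(positions)) positions <- seq(0, 1, length.out = n)
  gaps <- diff(positions)
  if (max(gaps) - min(gaps) > 1e-9 * max(gaps))
    stop("classical CSD requires regularly spaced electrodes")
  out <- rep(NA_real_, n)
  i <- 2:(n - 1)
  out[i] <- -0.5 * snapshot[i - 1] + snapshot[i] - 0.5 * snapshot[i + 1]
  out
}
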