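# Shared fixtures, built in code.

zcucModel <- function(mode = "half", electrodes = c(0, 1/3, 2/3, 1)) {
  buildModel(speciesGeometry("Zcuc"), electrodes, mode)
}

fineModel10 <- function(mode = "half", geometry = speciesGeometry("Zcuc")) {
  buildModel(geometry, seq(0, 1, length.out = 10), mode)
}

# Independent oracle for the forward integral: fully numeric nested
# quadrature of 1/sqrt(x^2 + y^2) over [x1,x2] x [y1,y2], outer integral
# split at the y = 0 singular line.  Shares no code with the package's
# closed form.
oracleRectIntegral <- function(x1, x2, y1, y2) {
  innerNum <- function(y) {
    vapply(y, function(yy)
      stats::integrate(function(x) 1 / sqrt(x^2 + yy^2), x1, x2,
                       rel.tol = 1e-12)$value, numeric(1))
  }
  piece <- function(lo, hi) {
    if (hi <= lo) return(0)
    stats::integrate(innerNum, lo, hi, rel.tol = 1e-8,
                     subdivisions = 2000L)$value
  }
  # split at the y = 0 line where the integrand has its (integrable)
  # log singularity when the x-range straddles the electrode
  if (y1 >= 0) piece(y1, y2)
  else if (y2 <= 0) piece(-y2, -y1)
  else piece(0, -y1) + piece(0, y2)
}

oracleTransferCoefficient <- function(model, i, j) {
  w <- compartmentWindows(model)
  q <- compartmentCircumferences(model)[j]
  Y <- if (lateralExtentMode(model) == "printed") q else q / 2
  xe <- electrodePositions(model)[i] * antennaLength(modelGeometry(model))
  oracleRectIntegral(w[j, 1] - xe, w[j, 2] - xe, -Y, Y) /
    (4 * pi * conductivity(modelGeometry(model)))
}

# Monte-Carlo estimate of the same integral (finite variance requires the
# electrode outside the source rectangle).
mcTransferCoefficient <- function(model, i, j, n = 1e6, seed = 42) {
  set.seed(seed)
  w <- compartmentWindows(model)
  q <- compartmentCircumferences(model)[j]
  Y <- if (lateralExtentMode(model) == "printed") q else q / 2
  xe <- electrodePositions(model)[i] * antennaLength(modelGeometry(model))
  x <- runif(n, w[j, 1], w[j, 2]) - xe
  y <- runif(n, -Y, Y)
  area <- unname(w[j, 2] - w[j, 1]) * 2 * Y
  mean(1 / sqrt(x^2 + y^2)) * area /
    (4 * pi * conductivity(modelGeometry(model)))
}

# A two-sink space-time CSD profile on a 7-compartment model: transient
# sinks (negative) at two compartments after the onset.
twoSinkCSD <- function(nTime, time, onset, compartments = 7,
                      sinks = c(4, 7), amps = c(-1, -0.8)) {
  csd <- matrix(0, nTime, compartments)
  shape <- exp(-(time - onset - 0.25)^2 / (2 * 0.1^2))
  shape[time <= onset] <- 0
  for (k in seq_along(sinks)) csd[, sinks[k]] <- amps[k] * shape
  csd
}
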