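#' Logit-normal spatial density
#'
#' Probability density on (0, 1) of a logistic-transformed Gaussian, the
#' bounded kernel used for sensilla spatial distributions along the
#' proximo-distal axis.  The class parameters are given in position units
#' (center and spread on the antenna), so the latent Gaussian parameters
#' are obtained by the delta method: latent mean \code{logit(center)} and
#' latent sd \code{sd / (center * (1 - center))}, which makes the local
#' spread near the center approximately \code{sd}.  The alternative
#' \code{"latent"} mode takes \code{sd} directly as the latent Gaussian sd.
#'
#' @param x evaluation positions; the density is 0 outside (0, 1) and at the
#'   boundary by continuity.
#' @param center distribution center, in (0, 1).
#' @param sd spatial spread (position units in \code{"delta"} mode).
#' @param mode latent-parameter mapping, \code{"delta"} (default) or
#'   \code{"latent"}.
#' @return density values; the density integrates to 1 over (0, 1).
#' @export
logitNormalDensity <- function(x, center, sd, mode = c("delta", "latent")) {
  mode <- match.arg(mode)
  if (center <= 0 || center >= 1) stop("center must be inside (0, 1)")
  if (sd <= 0) stop("sd must be positive")
  mu <- log(center / (1 - center))
  sl <- if (mode == "delta") sd / (center * (1 - center)) else sd
  out <- numeric(length(x))
  ok <- x > 0 & x < 1
  xo <- x[ok]
  out[ok] <- stats::dnorm(log(xo / (1 - xo)), mu, sl) / (xo * (1 - xo))
  out
}

#' Create a sensilla class
#'
#' @param name class label (e.g. \code{"ab3"}).
#' @param count sensilla of this class per antenna (fractional allowed).
#' @param center,sd parameters of the logit-normal spatial distribution
#'   (position units).
#' @param family \code{"basiconic"} or \code{"trichoid"}.
#' @param responses per-ORN response levels (consensual scaled units, e.g.
#'   from the DoOR database, supplied by the user); empty when unknown.
#' @return a [SensillaClass-class].
#' @export
sensillaClass <- function(name, count, center, sd,
                          family = c("basiconic", "trichoid"),
                          responses = numeric()) {
  family <- match.arg(family)
  new("SensillaClass", name = name, count = count, center = center,
      sd = sd, family = family, responses = responses)
}

setMethod("show", "SensillaClass", function(object) {
  cat(sprintf("SensillaClass %s (%s): count %.4g, center %.3g, sd %.3g, %d ORN responses\n",
              object@name, object@family, object@count, object@center,
              object@sd, length(object@responses)))
})

#' Default Drosophila melanogaster sensilla classes
#'
#' The 14 basiconic and trichoid classes of the female D. melanogaster
#' antenna with their per-antenna counts and logit-normal spatial
#' parameters.  Basiconic centers (other than ab3) are regularly interleaved
#' from 0.1 (ab1) to 0.85 (ab9) in proximal-to-distal order ab1, ab2, ab4,
#' ab6, ab5, ab7, ab8, ab10, ab9 with sd 0.1; ab3 sits proximally at center
#' 0.05 with sd 0.05.  Trichoid centers are 0.65, 0.70, 0.75, 0.80 for at1,
#' at3, at2, at4 with sd 0.15.  Response levels default to empty (user
#' supplied); at1 typically responds little to small esters and polar
#' compounds and is commonly left at zero.
#'
#' @return named list of [SensillaClass-class] objects.
#' @examples
#' cl <- defaultSensillaClasses()
#' cl$ab3
#' @export
defaultSensillaClasses <- function() {
  bNames <- c("ab1", "ab2", "ab4", "ab6", "ab5", "ab7", "ab8", "ab10", "ab9")
  bCounts <- c(39.825, 23, 14, 15, 34, 11.25, 18, 18, 24)
  bCenters <- seq(0.1, 0.85, length.out = 9)
  tNames <- c("at1", "at3", "at2", "at4")
  tCounts <- c(62.5, 27, 15, 19.5)
  tCenters <- c(0.65, 0.70, 0.75, 0.80)
  out <- c(
    list(sensillaClass("ab3", 8, 0.05, 0.05, "basiconic")),
    mapply(sensillaClass, bNames, bCounts, bCenters,
           MoreArgs = list(sd = 0.1, family = "basiconic")),
    mapply(sensillaClass, tNames, tCounts, tCenters,
           MoreArgs = list(sd = 0.15, family = "trichoid"))
  )
  names(out) <- vapply(out, function(x) x@name, character(1))
  out
}

#' Uniform evaluation grid on (0, 1)
#'
#' Open-interval grid by half-step offset, the default abscissa for density
#' curves.
#'
#' @param n number of points (default 1000).
#' @export
densityGrid <- function(n = 1000) seq(1 / (2 * n), 1 - 1 / (2 * n), length.out = n)

#' Sensilla density of one class
#'
#' Count-weighted logit-normal density: integrates to the class count, so a
#' uniform curve at value 100 would mean 100 sensilla on the antenna.
#'
#' @param class a [SensillaClass-class].
#' @param grid evaluation grid (normalized positions).
#' @param mode passed to [logitNormalDensity()].
#' @return density values (sensilla per unit antennal length).
#' @export
sensillaDensity <- function(class, grid = densityGrid(), mode = "delta") {
  class@count * logitNormalDensity(grid, class@center, class@sd, mode)
}

#' Response density along the antenna
#'
#' For each class, the summed per-ORN responses are multiplied by the
#' class's sensilla density; the class curves are summed.  The result is
#' linear and 1-homogeneous in the response table.  Classes without
#' response data contribute zero (with a notification).
#'
#' @param classes list of [SensillaClass-class] objects.
#' @param grid evaluation grid.
#' @param mode passed to [logitNormalDensity()].
#' @param quiet suppress the note about response-less classes.
#' @return a [ResponseDensityCurve-class].
#' @export
responseDensity <- function(classes, grid = densityGrid(), mode = "delta",
                            quiet = FALSE) {
  missing <- vapply(classes, function(cl) length(cl@responses) == 0, logical(1))
  if (any(missing) && !quiet)
    message("classes without response data treated as zero: ",
            paste(vapply(classes[missing], function(cl) cl@name, character(1)),
                  collapse = ", "))
  dens <- numeric(length(grid))
  for (cl in classes) {
    r <- sum(cl@responses)
    if (r != 0) dens <- dens + r * sensillaDensity(cl, grid, mode)
  }
  new("ResponseDensityCurve", grid = grid, density = dens)
}

#' @rdname responseDensity
#' @param x a \code{ResponseDensityCurve}.
#' @export
densityValues <- function(x) x@density

setMethod("show", "ResponseDensityCurve", function(object) {
  cat(sprintf("ResponseDensityCurve on %d grid points; peak %.4g at x = %.3g\n",
              length(object@grid), max(object@density),
              object@grid[which.max(object@density)]))
})

#' Average a density curve over model compartments
#'
#' Mean of the curve over each compartment window (normalized coordinates),
#' the quantity compared against per-compartment CSD responses.
#'
#' @param curve a [ResponseDensityCurve-class] (or numeric values with a
#'   \code{grid} attribute as produced internally).
#' @param model a [CompartmentModel-class] whose windows are taken in
#'   normalized coordinates.
#' @return per-compartment means.
#' @export
compartmentAverage <- function(curve, model) {
  grid <- curve@grid; dens <- curve@density
  win <- compartmentWindows(model) / antennaLength(modelGeometry(model))
  out <- numeric(nrow(win))
  for (i in seq_len(nrow(win))) {
    sel <- grid >= win[i, 1] & grid < win[i, 2]
    if (sum(sel) < 10)
      warning(sprintf("only %d grid points in compartment %d; use a finer grid",
                      sum(sel), i))
    out[i] <- mean(dens[sel])
  }
  out
}

#' Read a per-ORN response table and attach it to sensilla classes
#'
#' The table is delimited text with columns \code{sensillum_class},
#' \code{orn_id} and \code{response}.  Classes present in \code{classes}
#' but absent from the table keep empty responses (treated as zero by
#' [responseDensity()]).
#'
#' @param path path to the delimited file (any whitespace/comma separator
#'   that [utils::read.table()] with \code{header = TRUE, sep = ""} or
#'   \code{","} can parse; comma is tried first).
#' @param classes list of [SensillaClass-class] to decorate.
#' @return the updated class list.
#' @export
readResponseTable <- function(path, classes = defaultSensillaClasses()) {
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) utils::read.table(path, header = TRUE,
                                                        stringsAsFactors = FALSE))
  need <- c("sensillum_class", "orn_id", "response")
  if (!all(need %in% names(tab)))
    stop("response table must have columns: ", paste(need, collapse = ", "))
  for (nm in names(classes)) {
    rows <- tab$sensillum_class == nm
    if (any(rows)) classes[[nm]]@responses <- as.numeric(tab$response[rows])
  }
  classes
}
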