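#' Create an EAG recording
#'
#' @param time time axis (s), strictly increasing.
#' @param traces matrix of potentials (mV), one column per electrode.
#' @param samplingRate sampling rate in Hz; inferred from \code{time} when
#'   missing.
#' @param onsets stimulus onset times (s).
#' @param positions normalized electrode positions (one per column).
#' @param control optional control-stimulus traces on the same time base.
#' @return an [EAGRecording-class].
#' @export
eagRecording <- function(time, traces, samplingRate = NULL, onsets = numeric(),
                         positions = seq(0, 1, length.out = ncol(traces)),
                         control = NULL) {
  traces <- as.matrix(traces)
  if (is.null(samplingRate))
    samplingRate <- 1 / stats::median(diff(time))
  new("EAGRecording", time = time, traces = traces,
      samplingRate = samplingRate, onsets = onsets,
      positions = positions, control = control)
}

#' @rdname eagRecording
#' @param x an \code{EAGRecording}.
#' @export
recordingTraces <- function(x) x@traces

#' @rdname eagRecording
#' @export
recordingTime <- function(x) x@time

#' @rdname eagRecording
#' @export
stimulusOnsets <- function(x) x@onsets

setMethod("show", "EAGRecording", function(object) {
  cat(sprintf("EAGRecording: %d channels x %d samples at %g Hz, t in [%.3g, %.3g] s\n",
              ncol(object@traces), nrow(object@traces), object@samplingRate,
              min(object@time), max(object@time)))
  if (length(object@onsets))
    cat("  stimulus onsets (s):", paste(signif(object@onsets, 4), collapse = ", "), "\n")
  if (!is.null(object@control)) cat("  paired control recording attached\n")
})

## unit-area discrete Gaussian kernel; sd in samples
gaussKernel <- function(sdSamples) {
  r <- max(1L, ceiling(4 * sdSamples))
  k <- stats::dnorm(-r:r, sd = sdSamples)
  k / sum(k)
}

## convolve one trace with reflect padding so baselines are not dragged to 0
smoothTrace <- function(x, kernel) {
  r <- (length(kernel) - 1L) / 2L
  n <- length(x)
  pad <- c(x[pmin(r:1 + 1L, n)], x, x[pmax(n - (1:r), 1L)])
  stats::filter(pad, kernel, sides = 2)[(r + 1L):(r + n)]
}

#' Preprocess an EAG recording
#'
#' Gaussian smoothing (the standard 20 ms width) followed by sample-wise
#' subtraction of the identically preprocessed control recording, when one
#' is available.  "Width" is interpreted as the kernel standard deviation by
#' default; a FWHM interpretation is available since the convention differs
#' between laboratories.  Convolution uses reflect padding.
#'
#' @param recording an [EAGRecording-class].
#' @param control optional control [EAGRecording-class] (or matrix on the
#'   same time base); defaults to the recording's own \code{control} slot.
#' @param smoothingWidth kernel width in seconds (default 0.020).
#' @param widthMode \code{"sd"} (default) or \code{"fwhm"}.
#' @return a preprocessed [EAGRecording-class] (control slot cleared).
#' @export
preprocessEAG <- function(recording, control = recording@control,
                          smoothingWidth = 0.020,
                          widthMode = c("sd", "fwhm")) {
  widthMode <- match.arg(widthMode)
  if (smoothingWidth <= 0) stop("smoothingWidth must be positive")
  sdSec <- if (widthMode == "sd") smoothingWidth
           else smoothingWidth / (2 * sqrt(2 * log(2)))
  kernel <- gaussKernel(sdSec * recording@samplingRate)
  sm <- apply(recording@traces, 2, smoothTrace, kernel = kernel)
  if (!is.null(control)) {
    ctrl <- if (is(control, "EAGRecording")) control@traces else as.matrix(control)
    if (!identical(dim(ctrl), dim(recording@traces)))
      stop("control and stimulus recordings must share the same time base")
    sm <- sm - apply(ctrl, 2, smoothTrace, kernel = kernel)
  }
  eagRecording(recording@time, sm, recording@samplingRate,
               recording@onsets, recording@positions)
}

windowValues <- function(trace, time, from, to, openLeft, what) {
  sel <- if (openLeft) time > from & time <= to else time >= from & time < to
  if (time[1] > from || time[length(time)] < to)
    stop(sprintf("trace lacks the [%.3g, %.3g] s context needed for the %s window",
                 from, to, what))
  trace[sel]
}

#' EAG response amplitude
#'
#' Maximum negative peak in the 0.5 s after stimulus onset minus the average
#' value in the 0.5 s before it.  Responses are negative deflections, so
#' evoked responses give negative amplitudes; take the absolute value for
#' display if preferred.  Windows are half-open: the onset sample belongs to
#' the baseline side.
#'
#' @param trace one EAG trace (mV).
#' @param time matching time axis (s).
#' @param onset stimulus onset (s); needs 0.5 s of context on both sides.
#' @return amplitude in mV (negative for responses).
#' @export
eagAmplitude <- function(trace, time, onset) {
  base <- windowValues(trace, time, onset - 0.5, onset, FALSE, "pre-stimulus")
  post <- windowValues(trace, time, onset, onset + 0.5, TRUE, "post-stimulus")
  min(post) - mean(base)
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Area of a CSD response
#'
#' The CSD trace is sign-reversed and integrated over the response window
#' after onset (default 0 to 1.5 s, trapezoidal rule), so current sinks give
#' positive areas.  This is the default scalar quantification of a CSD
#' response.
#'
#' @param trace one compartment's CSD trace.
#' @param time time axis (s).
#' @param onset stimulus onset (s).
#' @param window integration bounds relative to onset (s).
#' @return the reversed integral (CSD units x s).
#' @export
csdResponseArea <- function(trace, time, onset, window = c(0, 1.5)) {
  sel <- time > onset + window[1] & time <= onset + window[2]
  if (time[length(time)] < onset + window[2] || time[1] > onset + window[1])
    stop(sprintf("trace lacks the %g s post-onset context for area integration",
                 window[2]))
  tt <- c(onset + window[1], time[sel])
  yy <- c(stats::approx(time, trace, onset + window[1])$y, trace[sel])
  trapezoid(tt, -yy)
}

#' Amplitude of a CSD response
#'
#' Minimum of the CSD signal in the 500 ms before onset minus the minimum in
#' the 500 ms after it; an evoked sink (post-onset dip) gives a positive
#' amplitude.
#'
#' @inheritParams csdResponseArea
#' @return amplitude in CSD units (positive for evoked sinks).
#' @export
csdResponseAmplitude <- function(trace, time, onset) {
  pre <- windowValues(trace, time, onset - 0.5, onset, FALSE, "pre-stimulus")
  post <- windowValues(trace, time, onset, onset + 0.5, TRUE, "post-stimulus")
  min(pre) - min(post)
}

#' Center of mass of positive responses
#'
#' Response-weighted mean position, using only positive responses (negative
#' values are clamped to zero; with \code{negatives = "exclude"} they are
#' dropped, which gives the identical result and is provided for symmetry
#' with common practice).  Localizes the activated antennal region from
#' per-compartment response areas or amplitudes.
#'
#' @param responses per-compartment response scalars (sinks counted
#'   positive, i.e. areas or amplitudes).
#' @param positions normalized compartment midpoints.
#' @param negatives how to treat negative responses.
#' @return the normalized position, or NA when no response is positive
#'   (undefined, deliberately not 0).
#' @examples
#' centerOfMass(c(2, 1, 0, 0), c(0.125, 0.375, 0.625, 0.875))
#' @export
centerOfMass <- function(responses, positions,
                         negatives = c("clamp", "exclude")) {
  negatives <- match.arg(negatives)
  if (length(responses) != length(positions))
    stop("responses and positions must have equal length")
  w <- if (negatives == "clamp") pmax(responses, 0)
       else ifelse(responses > 0, responses, 0)
  if (sum(w) <= 0) return(NA_real_)
  sum(w * positions) / sum(w)
}

#' Compare center-of-mass locations across stimuli
#'
#' Paired two-sided Wilcoxon signed-rank tests (exact distribution) between
#' every pair of stimuli, each row of \code{centers} being one individual.
#' Stimuli whose centers do not differ at \code{alpha} share a letter in the
#' compact letter display.
#'
#' @param centers matrix of per-individual centers of mass, one column per
#'   stimulus (column names label the stimuli).
#' @param alpha significance level for the letter grouping (default 0.05).
#' @return list with \code{p} (symmetric p-value matrix) and \code{letters}
#'   (per-stimulus letter labels).
#' @export
pairedCenterComparison <- function(centers, alpha = 0.05) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 2) stop("need at least two paired individuals")
  k <- ncol(centers)
  if (is.null(colnames(centers))) colnames(centers) <- paste0("S", seq_len(k))
  p <- matrix(1, k, k, dimnames = list(colnames(centers), colnames(centers)))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    pv <- stats::wilcox.test(centers[, a], centers[, b], paired = TRUE,
                             exact = TRUE)$p.value
    p[a, b] <- p[b, a] <- pv
  }
  list(p = p, letters = letterGroups(p >= alpha))
}

## compact letter display: greedy insert-absorb over the "not different"
## adjacency; adequate for the handful of stimuli used per session
letterGroups <- function(same) {
  k <- nrow(same)
  groups <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(same[i, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], i); placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  keep <- rep(TRUE, length(groups))
  for (g in seq_along(groups)) for (h in seq_along(groups))
    if (g != h && keep[h] && all(groups[[g]] %in% groups[[h]]) &&
        (length(groups[[g]]) < length(groups[[h]]) || g > h)) keep[g] <- FALSE
  groups <- groups[keep]
  out <- character(k)
  for (g in seq_along(groups))
    out[groups[[g]]] <- paste0(out[groups[[g]]], letters[g])
  stats::setNames(out, rownames(same))
}
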