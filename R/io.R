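## Delimited-text readers and writers.  Trace files are CSV with a `time`
## column and one column per channel; acquisition metadata travels in a
## JSON (or YAML) sidecar so the trace file stays a plain table that any
## rig software can dump.

readSidecar <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML sidecars requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read and write EAG recordings
#'
#' \code{writeRecording()} writes the traces as CSV (\code{time} + one
#' column per channel, mV and s) plus a JSON metadata sidecar with keys
#' \code{positions}, \code{onsets_s}, \code{sampling_hz} and optionally
#' \code{control_path} (control traces are written next to the main file).
#' \code{readRecording()} parses the pair back, validates the declared
#' channel count and warns when the sampling rate differs from the 500 Hz
#' convention.  The roundtrip is lossless to printed precision (15
#' significant digits).
#'
#' @param recording an [EAGRecording-class].
#' @param path path of the CSV trace file.
#' @param metadataPath path of the sidecar; defaults to \code{path} with a
#'   \code{.json} extension.
#' @return \code{readRecording()}: an [EAGRecording-class].
#' @export
writeRecording <- function(recording, path,
                           metadataPath = sub("\\.[^.]+$", ".json", path)) {
  df <- data.frame(time = recording@time, recording@traces)
  names(df) <- c("time", paste0("ch", seq_len(ncol(recording@traces))))
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  meta <- list(positions = recording@positions, onsets_s = recording@onsets,
               sampling_hz = recording@samplingRate)
  if (!is.null(recording@control)) {
    ctrlPath <- sub("(\\.[^.]+)$", "_control\\1", path)
    ctrl <- data.frame(time = recording@time, recording@control)
    names(ctrl) <- names(df)
    utils::write.csv(format(ctrl, digits = 15, trim = TRUE), ctrlPath,
                     row.names = FALSE, quote = FALSE)
    meta$control_path <- basename(ctrlPath)
  }
  jsonlite::write_json(meta, metadataPath, auto_unbox = TRUE, digits = NA)
  invisible(c(path, metadataPath))
}

#' @rdname writeRecording
#' @export
readRecording <- function(path, metadataPath = sub("\\.[^.]+$", ".json", path)) {
  if (!file.exists(metadataPath))
    stop("metadata sidecar not found: ", metadataPath,
         " (required keys: positions, sampling_hz; optional: onsets_s, control_path)")
  meta <- readSidecar(metadataPath)
  need <- c("positions", "sampling_hz")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("metadata is missing required keys: ", paste(missing, collapse = ", "))
  tab <- utils::read.csv(path)
  if (names(tab)[1] != "time") stop("first column of a trace file must be 'time'")
  if (any(diff(tab$time) <= 0)) stop("time column must be strictly increasing")
  traces <- as.matrix(tab[, -1, drop = FALSE])
  if (ncol(traces) != length(meta$positions))
    stop("trace file has ", ncol(traces), " channels but the metadata declares ",
         length(meta$positions), " positions")
  fs <- meta$sampling_hz
  if (abs(fs - 500) > 1e-6)
    warning("sampling rate is ", fs, " Hz, not the conventional 500 Hz")
  ctrl <- NULL
  if (!is.null(meta$control_path)) {
    ctrlTab <- utils::read.csv(file.path(dirname(path), meta$control_path))
    ctrl <- as.matrix(ctrlTab[, -1, drop = FALSE])
  }
  eagRecording(tab$time, traces, fs,
               onsets = if (is.null(meta$onsets_s)) numeric() else meta$onsets_s,
               positions = meta$positions, control = ctrl)
}

#' Read and write CSD maps
#'
#' Delimited text with a \code{time} column and one column per compartment,
#' headed by the normalized compartment midpoints.
#'
#' @param map a [CSDMap-class].
#' @param path output path.
#' @param model a [CompartmentModel-class] used to re-attach the
#'   compartment structure on reading.
#' @export
writeCSDMap <- function(map, path) {
  df <- data.frame(time = map@time, map@values)
  names(df) <- c("time", sprintf("x%.4f", compartmentMidpoints(map@model)))
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCSDMap
#' @export
readCSDMap <- function(path, model) {
  tab <- utils::read.csv(path)
  new("CSDMap", time = tab$time, values = as.matrix(tab[, -1, drop = FALSE]),
      model = model)
}

#' Read an antenna geometry config
#'
#' JSON or YAML with keys \code{species}, \code{length_mm}, \code{width_mm},
#' \code{thickness_mm} (default width), \code{shape} (default cylinder),
#' \code{taper_ratio} (default 1) and \code{sigma} (default 10).
#'
#' @param path config file path.
#' @return an [AntennaGeometry-class].
#' @export
readGeometry <- function(path) {
  cfg <- readSidecar(path)
  need <- c("species", "length_mm", "width_mm")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("geometry config is missing required keys: ",
         paste(missing, collapse = ", "))
  antennaGeometry(cfg$species, length = cfg$length_mm, width = cfg$width_mm,
                  thickness = if (is.null(cfg$thickness_mm)) cfg$width_mm
                              else cfg$thickness_mm,
                  shape = if (is.null(cfg$shape)) "cylinder" else cfg$shape,
                  taperRatio = if (is.null(cfg$taper_ratio)) 1 else cfg$taper_ratio,
                  sigma = if (is.null(cfg$sigma)) 10 else cfg$sigma)
}

#' Detect compound windows on an FID trace
#'
#' Retention-time windows are the contiguous runs where the flame
#' ionization detector signal exceeds baseline median + k MAD.
#'
#' @param fid FID trace (arbitrary units).
#' @param time matching time axis (s).
#' @param k threshold multiplier (default 5).
#' @param minDuration minimum window duration (s) to keep.
#' @return data.frame with columns \code{start}, \code{end} (s).
#' @export
fidWindows <- function(fid, time, k = 5, minDuration = 0) {
  thr <- stats::median(fid) + k * stats::mad(fid)
  above <- fid > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  out <- data.frame(start = time[starts[keep]], end = time[ends[keep]])
  out[out$end - out$start >= minDuration, , drop = FALSE]
}

#' CSD spatial maps per GC retention-time window
#'
#' Estimates the CSD at every time point of a GC-EAD recording and, for
#' each compound's retention-time window, integrates the sign-reversed CSD
#' over the window in each compartment, yielding one spatial response map
#' per compound.
#'
#' @param recording an [EAGRecording-class] aligned with the GC effluent.
#' @param model a [CompartmentModel-class] matching the channel count.
#' @param windows data.frame with \code{start}, \code{end} (s) and
#'   optionally \code{compound}; or NULL to derive them from \code{fid}.
#' @param fid optional FID trace on the recording's time base.
#' @param fidOffset constant time shift (s) added to FID-derived windows to
#'   compensate the transfer-line delay.
#' @param k threshold multiplier for [fidWindows()].
#' @return list with \code{windows} and \code{maps}, a compounds x
#'   compartments matrix of reversed-integral responses.
#' @export
gcEadCSD <- function(recording, model, windows = NULL, fid = NULL,
                     fidOffset = 0, k = 5) {
  if (is.null(windows)) {
    if (is.null(fid)) stop("supply either retention-time windows or an FID trace")
    windows <- fidWindows(fid, recording@time, k)
    windows$start <- windows$start + fidOffset
    windows$end <- windows$end + fidOffset
  }
  if (!nrow(windows)) stop("no retention-time windows")
  if (is.null(windows$compound))
    windows$compound <- paste0("w", seq_len(nrow(windows)))
  if (any(windows$start < recording@time[1]) ||
      any(windows$end > recording@time[length(recording@time)]))
    stop("a retention-time window falls outside the recording")
  ord <- order(windows$start)
  if (any(windows$start[ord][-1] < windows$end[ord][-nrow(windows)]))
    stop("retention-time windows must not overlap")
  map <- estimateCSDTimeseries(model, recording)
  maps <- t(vapply(seq_len(nrow(windows)), function(i)
    apply(map@values, 2, function(tr)
      csdResponseArea(tr, map@time, onset = windows$start[i],
                      window = c(0, windows$end[i] - windows$start[i]))),
    numeric(nCompartments(model))))
  rownames(maps) <- windows$compound
  colnames(maps) <- sprintf("x%.3f", compartmentMidpoints(model))
  list(windows = windows, maps = maps, csdMap = map)
}
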