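# Mu-rhythm band-pass filtering and stage slicing. The pipeline order is
# fixed: filter the whole trial first, then slice the stage window, so
# filter transients never sit at stage boundaries.

# zero-phase Butterworth band-pass of a single vector
.bandpassVector <- function(x, low, high, fs, order = 4) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' The four trial stages
#'
#' Default stage windows of a trial given its boundaries: preparation
#' \[0, 3), cue \[3, 4), imagery \[4, 8) and rest \[8, 10) seconds. Windows
#' are half-open in samples: \[start * fs, end * fs).
#'
#' @param bounds numeric vector of 5 increasing stage boundaries, seconds.
#' @return data.frame with columns `name`, `start`, `end`.
#' @export
stageWindows <- function(bounds = c(0, 3, 4, 8, 10)) {
  stopifnot(length(bounds) == 5, all(diff(bounds) > 0))
  data.frame(name = c("preparation", "cue", "imagery", "rest"),
             start = bounds[1:4], end = bounds[2:5],
             stringsAsFactors = FALSE)
}

#' Band-pass filter a recording to the mu rhythm
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass of the
#' given order to every channel. The default 8-13 Hz band isolates the mu
#' rhythm used for network construction.
#'
#' @param rec a [Recording-class].
#' @param low,high band edges, Hz; must satisfy 0 < low < high < fs/2.
#' @param order Butterworth order (4 by default; forward-backward
#'   application doubles the effective rolloff).
#' @return filtered [Recording-class] of the same shape.
#' @export
bandpassMu <- function(rec, low = 8, high = 13, order = 4) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop(sprintf("infeasible band [%g, %g] Hz for fs = %g Hz: need 0 < low < high < fs/2",
                 low, high, fs))
  out <- rec
  out@data <- t(apply(rec@data, 1, .bandpassVector, low = low,
                      high = high, fs = fs, order = order))
  out@history <- c(rec@history, sprintf("bandpass(%g,%g)", low, high))
  out
}

#' Extract a stage window from a recording
#'
#' Slices the half-open sample window \[start * fs, end * fs) of a named
#' stage (resolved against the recording's stage boundaries) or of an
#' explicit `c(start, end)` window in seconds. Channel count, labels and
#' metadata are carried over.
#'
#' @param rec a [Recording-class].
#' @param stage stage name (`"preparation"`, `"cue"`, `"imagery"`,
#'   `"rest"`) or numeric `c(start, end)` seconds.
#' @return the sliced [Recording-class].
#' @examples
#' rec <- simulateTrial(simulationConfig(), "S")
#' ncol(recData(extractStage(rec, "imagery")))  # 1000
#' @export
extractStage <- function(rec, stage) {
  stopifnot(is(rec, "Recording"))
  if (is.character(stage)) {
    win <- stageWindows(rec@stageBounds)
    row <- win[win$name == stage, ]
    if (nrow(row) != 1)
      stop("unknown stage '", stage, "'; must be one of ",
           paste(win$name, collapse = ", "))
    start <- row$start
    end <- row$end
  } else {
    stopifnot(is.numeric(stage), length(stage) == 2, stage[1] < stage[2])
    start <- stage[1]
    end <- stage[2]
  }
  fs <- rec@fs
  i0 <- floor(start * fs) + 1
  i1 <- floor(end * fs)
  if (i0 < 1 || i1 > ncol(rec@data))
    stop(sprintf("window [%g, %g) s outside recording duration %g s",
                 start, end, ncol(rec@data) / fs))
  out <- rec
  out@data <- rec@data[, i0:i1, drop = FALSE]
  out@stageBounds <- c(start, end)
  out@history <- c(rec@history, sprintf("slice(%g,%g)", start, end))
  out
}

#' Optional artifact-removal hook
#'
#' Applies a user-supplied recording-to-recording transform (for example
#' an ocular-artifact cleaner); the default is the identity. The package
#' does not ship an ICA-based EOG remover.
#'
#' @param rec a [Recording-class].
#' @param fun function taking and returning a [Recording-class].
#' @return transformed [Recording-class].
#' @export
removeArtifacts <- function(rec, fun = identity) {
  out <- fun(rec)
  stopifnot(is(out, "Recording"))
  out
}
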