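## Internal helpers shared across modules.
##
## Conventions used throughout the package: time is expressed in milliseconds
## from acquisition start, samples are 0-based in time (row i holds the sample
## at (i - 1) * 1000 / fs ms) and all windows are half-open [start, end).

#' Sentinel threshold marking a Not Active channel
#'
#' Channels that never sustain a crossing of the low threshold are assigned
#' this sentinel as their high threshold. It lies above the 5 V full scale of
#' the envelope sensors, so the signal can never reach it.
#'
#' @format A numeric scalar (10, volts).
#' @export
NA_VALUE <- 10

#' Gesture task labels in canonical order
#'
#' The four gesture tasks, in the fixed order used when concatenating the
#' per-task partial sequences into the 12-element feature vector.
#'
#' @format A character vector of length 4.
#' @export
GESTURE_TASKS <- c("Spherical", "Tip", "Platform", "Point")

#' @rdname GESTURE_TASKS
#' @format NULL
#' @export
REST_LABEL <- "Rest"

## full-scale output of the envelope sensors, volts
FULL_SCALE <- 5

.isSentinel <- function(v) v >= NA_VALUE - 1e-9

## row index of the sample at time `ms` (0-based ms -> 1-based row)
.msToRow <- function(ms, fs) floor(ms * fs / 1000 + 1e-9) + 1L

.rowToMs <- function(row, fs) (row - 1) * 1000 / fs

## rows covering the half-open window [fromMs, toMs)
.windowRows <- function(fromMs, toMs, fs, n = Inf, what = "window") {
  i0 <- floor(fromMs * fs / 1000 + 1e-9) + 1L
  i1 <- as.integer(ceiling(toMs * fs / 1000 - 1e-9))
  if (i1 < i0)
    stop(sprintf("empty %s [%g, %g) ms", what, fromMs, toMs))
  if (i0 < 1L || i1 > n)
    stop(sprintf("%s [%g, %g) ms overruns the recording", what, fromMs, toMs))
  seq.int(i0, i1)
}

## reproducible per-item seeds derived from a master seed, kept below 2^31
.deriveSeeds <- function(seed, n) {
  (as.double(seed) %% 2147483647 * 48271 + 104729 * seq_len(n)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
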