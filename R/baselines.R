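## Comparison feature sets: the envelope in the transient state (ETS),
## steady-state mean-absolute-value features (ESS), and the class-selection
## timing comparison between the sequence method and the steady state.

#' Transient-envelope (ETS) features
#'
#' Per channel, mean envelope in consecutive bins over a window starting at
#' the Start of Activation, concatenated channel-wise. With the default
#' 10 ms bins a 300 ms window yields 6 x 30 = 180 features; \code{binMs = 1}
#' at 1 kHz reproduces the raw samples (6 x 300).
#'
#' @param rec An \linkS4class{EnvelopeRecording}.
#' @param soaMs Start of Activation (ms).
#' @param windowMs Window length (ms).
#' @param binMs Bin length (ms); must divide \code{windowMs}.
#' @return Numeric vector of length \code{6 * windowMs / binMs}.
#' @export
etsFeatures <- function(rec, soaMs, windowMs = 300, binMs = 10) {
  if (windowMs %% binMs != 0) stop("'binMs' must divide 'windowMs'")
  fs <- sampleRate(rec)
  x <- samples(rec)
  rows <- .windowRows(soaMs, soaMs + windowMs, fs, nrow(x), "ETS window")
  nBins <- windowMs / binMs
  perBin <- length(rows) / nBins
  if (perBin != round(perBin)) stop("bins must hold a whole number of samples")
  binIdx <- rep(seq_len(nBins), each = perBin)
  out <- unlist(lapply(1:6, function(ch)
    as.numeric(tapply(x[rows, ch], binIdx, mean))), use.names = FALSE)
  names(out) <- paste0("emg", rep(1:6, each = nBins), "_b",
                       rep(seq_len(nBins), 6))
  out
}

#' Steady-state (ESS) features and anchor
#'
#' The steady-state anchor approximates the start of the flattened portion
#' of the trial as the time of the first absolute envelope peak among the 6
#' channels (the global maximum sample, earliest if repeated). The features
#' are the per-channel mean absolute value over a window starting at the
#' anchor.
#'
#' @param rec An \linkS4class{EnvelopeRecording}.
#' @param windowMs MAV window length (ms).
#' @return List with \code{mav} (numeric length 6), \code{tPeakMs} and
#'   \code{channelOfPeak}.
#' @export
essFeatures <- function(rec, windowMs = 100) {
  fs <- sampleRate(rec)
  x <- samples(rec)
  rowMax <- do.call(pmax, lapply(1:6, function(ch) x[, ch]))
  peakRow <- which.max(rowMax)
  tPeak <- .rowToMs(peakRow, fs)
  chPeak <- which.max(x[peakRow, ])
  rows <- .windowRows(tPeak, tPeak + windowMs, fs, nrow(x), "MAV window")
  mav <- colMeans(abs(x[rows, , drop = FALSE]))
  names(mav) <- paste0("emg", 1:6)
  list(mav = mav, tPeakMs = tPeak, channelOfPeak = as.integer(chPeak))
}

#' Build a baseline feature table (ETS or ESS)
#'
#' @param recordings Named list of acquisitions.
#' @param annotations Matching \linkS4class{OnsetAnnotation} list (needed
#'   for ETS; acquisitions without a SoA are omitted).
#' @param kind \code{"ets"} or \code{"ess"}.
#' @param ... Passed to \code{\link{etsFeatures}} / \code{\link{essFeatures}}.
#' @return A \linkS4class{FeatureTable}.
#' @export
baselineFeatureTable <- function(recordings, annotations, kind = c("ets", "ess"),
                                 ...) {
  kind <- match.arg(kind)
  keep <- !vapply(annotations, function(a) is.na(soaMs(a)), logical(1))
  rows <- lapply(which(keep), function(i) {
    if (kind == "ets")
      etsFeatures(recordings[[i]], soaMs(annotations[[i]]), ...)
    else essFeatures(recordings[[i]], ...)$mav
  })
  ids <- names(recordings)[keep] %||% sprintf("rec_%03d", which(keep))
  featureTable(do.call(rbind, rows),
               vapply(recordings[keep], recLabel, character(1)),
               ids, kind = kind)
}

#' Class-selection timing comparison of one acquisition
#'
#' The sequence method can select a class at the last activation of the
#' partial sequence; the steady-state method no earlier than the
#' steady-state anchor. Both elapsed times are measured from the Start of
#' Activation.
#'
#' @param soaMs Start of Activation (ms).
#' @param crossingTimesMs Absolute crossing times (ms) of the partial
#'   activation sequence (at most the first three activations are used).
#' @param anchorMs Steady-state anchor time (ms).
#' @param keep Activations retained in the partial sequence.
#' @return List with \code{tSeqMs}, \code{tEssMs} and
#'   \code{gapMs = tEssMs - tSeqMs}.
#' @export
timingComparison <- function(soaMs, crossingTimesMs, anchorMs, keep = 3L) {
  if (!length(crossingTimesMs))
    stop("at least one activation is required in the partial sequence")
  used <- sort(crossingTimesMs)[seq_len(min(keep, length(crossingTimesMs)))]
  tSeq <- max(used) - soaMs
  tEss <- anchorMs - soaMs
  list(tSeqMs = tSeq, tEssMs = tEss, gapMs = tEss - tSeq)
}
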