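## Double-threshold onset detection: rest statistics, TH_Low = mu + x * sigma,
## the 50 ms sustain rule, Not Active flagging, and the x-tuning experiment.

#' Estimate the dataset rest model and low threshold
#'
#' Rest mean and standard deviation are pooled over all channels and all
#' recordings within the rest window, giving a single low threshold per
#' dataset.
#'
#' @param recordings List of \linkS4class{EnvelopeRecording} objects.
#' @param restWindowMs Half-open rest window (ms), default the guaranteed
#'   initial [0, 500) rest span.
#' @param x Threshold multiplier.
#' @return A \linkS4class{RestModel}.
#' @export
estimateRestModel <- function(recordings, restWindowMs = c(0, 500), x = 15) {
  if (!length(recordings)) stop("empty recording list")
  pooled <- unlist(lapply(recordings, function(rec) {
    rows <- .windowRows(restWindowMs[1], restWindowMs[2], sampleRate(rec),
                        nrow(samples(rec)), "rest window")
    as.numeric(samples(rec)[rows, ])
  }), use.names = FALSE)
  restModel(mean(pooled), stats::sd(pooled), x)
}

## start rows of runs of `x > th` lasting at least nSustain samples
.sustainedRunStarts <- function(x, th, nSustain) {
  r <- rle(x > th)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts[r$values & r$lengths >= nSustain]
}

#' Detect the Start of Activation of one acquisition
#'
#' A channel crosses when it exceeds the low threshold throughout a sustain
#' window (default 50 ms); the crossing time is the first sample of that
#' window. The Start of Activation is the earliest crossing over channels;
#' channels with no sustained crossing anywhere in the recording are flagged
#' Not Active. No crossing on any channel leaves the SoA absent (a Rest
#' acquisition).
#'
#' @param rec An \linkS4class{EnvelopeRecording}.
#' @param rest A \linkS4class{RestModel}.
#' @param sustainMs Sustain window length (ms), >= 1.
#' @param searchWindowMs Optional half-open window (ms) the crossing must
#'   start in; default the whole recording.
#' @return An \linkS4class{OnsetAnnotation}.
#' @export
detectSoa <- function(rec, rest, sustainMs = 50, searchWindowMs = NULL) {
  fs <- sampleRate(rec)
  x <- samples(rec)
  nSustain <- max(1L, round(sustainMs * fs / 1000))
  if (sustainMs < 1) stop("'sustainMs' must be >= 1 ms")
  if (nSustain > nrow(x)) stop("sustain window longer than the recording")
  if (is.null(searchWindowMs)) searchWindowMs <- c(0, durationMs(rec))
  th <- thLow(rest)
  flags <- logical(6)
  crossing <- rep(NA_real_, 6)
  for (ch in 1:6) {
    starts <- .sustainedRunStarts(x[, ch], th, nSustain)
    flags[ch] <- length(starts) > 0L
    tms <- .rowToMs(starts, fs)
    tms <- tms[tms >= searchWindowMs[1] & tms < searchWindowMs[2]]
    if (length(tms)) crossing[ch] <- tms[1]
  }
  soa <- if (all(is.na(crossing))) NA_real_ else min(crossing, na.rm = TRUE)
  new("OnsetAnnotation", soaMs = soa, activeFlags = flags,
      firstCrossingMs = crossing)
}

#' Tune the low-threshold multiplier on false activations
#'
#' For each candidate multiplier the false-activation rate is the fraction
#' of acquisitions with a sustained low-threshold crossing starting inside
#' the initial rest interval (default the first 100 ms). The selected
#' multiplier is the smallest candidate with a rate below 5\%.
#'
#' @param recordings List of \linkS4class{EnvelopeRecording} objects.
#' @param candidates Candidate multipliers, default \code{c(2, 5, 10, 15)}.
#' @param falseWindowMs Half-open window (ms) in which a crossing counts as
#'   false, default [0, 100).
#' @param restWindowMs Rest window for the pooled statistics.
#' @param sustainMs Sustain window (ms).
#' @param bound Acceptable false-activation rate (fraction), default 0.05.
#' @return List with \code{rates} (named fraction per candidate),
#'   \code{selected} (smallest admissible candidate, NA if none), and the
#'   pooled \code{mu} and \code{sigma}.
#' @export
tuneX <- function(recordings, candidates = c(2, 5, 10, 15),
                  falseWindowMs = c(0, 100), restWindowMs = c(0, 500),
                  sustainMs = 50, bound = 0.05) {
  if (!length(recordings)) stop("empty recording list")
  base <- estimateRestModel(recordings, restWindowMs, x = 0)
  rates <- vapply(candidates, function(x) {
    rm <- restModel(base@mu, base@sigma, x)
    hits <- vapply(recordings, function(rec) {
      ann <- detectSoa(rec, rm, sustainMs = sustainMs,
                       searchWindowMs = falseWindowMs)
      !is.na(soaMs(ann))
    }, logical(1))
    mean(hits)
  }, numeric(1))
  names(rates) <- as.character(candidates)
  ok <- candidates[rates < bound]
  list(rates = rates, selected = if (length(ok)) min(ok) else NA_real_,
       mu = base@mu, sigma = base@sigma)
}
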