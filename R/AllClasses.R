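## S4 classes for the activation-sequence pipeline.

#' GestureProfile: ground-truth description of one gesture for the simulator
#'
#' A gesture is defined by the subset of the six envelope channels it
#' recruits, the order in which they activate, the mean delay of each
#' activation after movement onset, and the plateau amplitude each channel
#' reaches. The Rest condition is the profile with no active channels.
#'
#' @slot name Gesture label.
#' @slot activeChannels Integer subset of 1..6 (empty for Rest).
#' @slot order Permutation of \code{activeChannels}: ground-truth activation
#'   order.
#' @slot meanDelays Mean delay (ms) after movement onset of each channel in
#'   \code{order}; non-negative and non-decreasing.
#' @slot delayJitterSd Standard deviation (ms) of the per-repetition delay
#'   jitter.
#' @slot plateauAmplitudes Length-6 plateau amplitude (V); zero on inactive
#'   channels.
#' @slot amplitudeJitterCv Coefficient of variation of the slow multiplicative
#'   plateau jitter.
#' @slot riseTime 10--90\% rise time (ms) of the logistic rise to plateau.
#'
#' @export
setClass("GestureProfile",
  representation(
    name = "character",
    activeChannels = "integer",
    order = "integer",
    meanDelays = "numeric",
    delayJitterSd = "numeric",
    plateauAmplitudes = "numeric",
    amplitudeJitterCv = "numeric",
    riseTime = "numeric"
  )
)

setValidity("GestureProfile", function(object) {
  msg <- character()
  k <- length(object@order)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!setequal(object@order, object@activeChannels) ||
      anyDuplicated(object@order))
    msg <- c(msg, "'order' must be a permutation of 'activeChannels'")
  if (k && (any(object@order < 1L) || any(object@order > 6L)))
    msg <- c(msg, "channels must lie in 1..6")
  if (length(object@meanDelays) != k)
    msg <- c(msg, "'meanDelays' must align with 'order'")
  if (k && (any(object@meanDelays < 0) || is.unsorted(object@meanDelays)))
    msg <- c(msg, "'meanDelays' must be non-negative and non-decreasing")
  if (length(object@plateauAmplitudes) != 6L ||
      any(object@plateauAmplitudes < 0))
    msg <- c(msg, "'plateauAmplitudes' must be 6 non-negative volts")
  if (k && any(object@plateauAmplitudes[object@order] <= 0))
    msg <- c(msg, "active channels need a positive plateau amplitude")
  if (object@delayJitterSd < 0 || object@amplitudeJitterCv < 0)
    msg <- c(msg, "jitter parameters must be non-negative")
  if (object@riseTime <= 0)
    msg <- c(msg, "'riseTime' must be positive")
  if (length(msg)) msg else TRUE
})

#' NoiseModel: rest-phase envelope noise
#'
#' The rest-phase envelope is modelled as temporally correlated
#' (first-order autoregressive) noise around a positive mean, mimicking the
#' smoothed output of commercial envelope sensors. Correlated noise is what
#' makes sustained spurious crossings at small threshold multipliers
#' possible, as in real recordings.
#'
#' @slot restMean Mean rest amplitude (V).
#' @slot restSd Standard deviation of the rest amplitude (V).
#' @slot correlationTime Autocorrelation time constant (ms) of the rest
#'   noise; 0 gives white noise.
#'
#' @export
setClass("NoiseModel",
  representation(restMean = "numeric", restSd = "numeric",
                 correlationTime = "numeric")
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@restMean < 0) msg <- c(msg, "'restMean' must be non-negative")
  if (object@restSd < 0) msg <- c(msg, "'restSd' must be non-negative")
  if (object@correlationTime < 0)
    msg <- c(msg, "'correlationTime' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' EnvelopeRecording: one labelled multichannel envelope acquisition
#'
#' Holds the time-by-channel sample matrix of a single acquisition together
#' with its sampling metadata, gesture label, and (for synthetic data) the
#' generator ground truth.
#'
#' @slot samples Numeric matrix (time x 6 channels), volts, in [0, 5].
#' @slot fs Sampling frequency (Hz).
#' @slot label Gesture label.
#' @slot subjectId Subject identifier.
#' @slot truth List with ground-truth fields (\code{onsetMs}, \code{order},
#'   \code{activeChannels}, \code{startTimesMs}) or empty for real data.
#'
#' @export
setClass("EnvelopeRecording",
  representation(
    samples = "matrix",
    fs = "numeric",
    label = "character",
    subjectId = "character",
    truth = "list"
  )
)

setValidity("EnvelopeRecording", function(object) {
  msg <- character()
  if (ncol(object@samples) != 6L)
    msg <- c(msg, "recordings must have exactly 6 channels")
  if (!is.numeric(object@samples) || anyNA(object@samples))
    msg <- c(msg, "samples must be numeric and complete")
  else if (min(object@samples) < 0 || max(object@samples) > FULL_SCALE)
    msg <- c(msg, sprintf("samples must lie in [0, %g] V", FULL_SCALE))
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "'fs' must be a positive scalar")
  if (length(object@label) != 1L)
    msg <- c(msg, "'label' must be a single string")
  if (length(msg)) msg else TRUE
})

#' RestModel: rest statistics and the low activation threshold
#'
#' The low threshold is \code{thLow = mu + x * sigma} where \code{mu} and
#' \code{sigma} are the mean and standard deviation of the envelope in the
#' rest state, pooled over channels and acquisitions of a dataset, and
#' \code{x} is the tuned multiplier.
#'
#' @slot mu Rest mean (V).
#' @slot sigma Rest standard deviation (V).
#' @slot x Threshold multiplier (dimensionless).
#' @slot thLow Low threshold (V), always \code{mu + x * sigma}.
#'
#' @export
setClass("RestModel",
  representation(mu = "numeric", sigma = "numeric", x = "numeric",
                 thLow = "numeric")
)

setValidity("RestModel", function(object) {
  msg <- character()
  if (object@sigma < 0) msg <- c(msg, "'sigma' must be non-negative")
  if (abs(object@thLow - (object@mu + object@x * object@sigma)) > 1e-12)
    msg <- c(msg, "'thLow' must equal mu + x * sigma")
  if (length(msg)) msg else TRUE
})

#' OnsetAnnotation: Start of Activation and channel activity flags
#'
#' Per-acquisition result of the double-threshold onset detector: the Start
#' of Activation (earliest sustained low-threshold crossing over channels),
#' one activity flag per channel, and each channel's first sustained
#' crossing time.
#'
#' @slot soaMs Start of Activation (ms) or NA when no channel qualifies
#'   (interpreted as Rest).
#' @slot activeFlags Logical length 6: channel ever sustained above the low
#'   threshold.
#' @slot firstCrossingMs Numeric length 6: first sustained crossing time
#'   (ms) inside the search window, NA when none.
#'
#' @export
setClass("OnsetAnnotation",
  representation(soaMs = "numeric", activeFlags = "logical",
                 firstCrossingMs = "numeric")
)

setValidity("OnsetAnnotation", function(object) {
  msg <- character()
  if (length(object@activeFlags) != 6L || length(object@firstCrossingMs) != 6L)
    msg <- c(msg, "flags and crossing times must have length 6")
  if (any(!object@activeFlags & !is.na(object@firstCrossingMs)))
    msg <- c(msg, "inactive channels cannot have a crossing time")
  if (length(object@soaMs) != 1L)
    msg <- c(msg, "'soaMs' must be a single value")
  else if (all(is.na(object@firstCrossingMs))) {
    if (!is.na(object@soaMs))
      msg <- c(msg, "'soaMs' must be NA when no channel crossed")
  } else if (is.na(object@soaMs) ||
             abs(object@soaMs - min(object@firstCrossingMs, na.rm = TRUE)) >
             1e-9)
    msg <- c(msg, "'soaMs' must equal the earliest channel crossing")
  if (length(msg)) msg else TRUE
})

#' ThresholdLadder: descending high-threshold candidates for one channel
#'
#' The ladder starts at 80\% of the mean in-window peak and decreases
#' multiplicatively by 10\% per step; candidates at or below the low
#' threshold are replaced by the \code{NA_VALUE} sentinel. With the
#' 50\%-of-peak floor the ladder admits at most 5 steps.
#'
#' @slot channel Channel index 1..6.
#' @slot values Candidate thresholds (V), length \code{nSteps}; entries may
#'   be the sentinel.
#' @slot nSteps Number of candidates (2..5).
#'
#' @export
setClass("ThresholdLadder",
  representation(channel = "integer", values = "numeric", nSteps = "integer")
)

setValidity("ThresholdLadder", function(object) {
  msg <- character()
  if (object@nSteps < 2L || object@nSteps > 5L)
    msg <- c(msg, "'nSteps' must lie in 2..5")
  if (length(object@values) != object@nSteps)
    msg <- c(msg, "'values' must have length nSteps")
  real <- object@values[!.isSentinel(object@values)]
  if (length(real) > 1L &&
      any(abs(real[-1] / real[-length(real)] - 0.9) > 1e-9))
    msg <- c(msg, "consecutive candidates must decrease by 10%")
  if (length(object@channel) != 1L || object@channel < 1L ||
      object@channel > 6L)
    msg <- c(msg, "'channel' must lie in 1..6")
  if (length(msg)) msg else TRUE
})

#' ThresholdVector: per-task representative high thresholds
#'
#' One high threshold per channel for a given task; entries may be the
#' \code{NA_VALUE} sentinel for Not Active channels. The four task vectors
#' form the 4 x 6 representative threshold matrix.
#'
#' @slot task Gesture label the vector belongs to.
#' @slot values Numeric length 6 (V, possibly sentinel).
#' @slot nSteps Ladder depth (2..5) the vector was searched over.
#'
#' @export
setClass("ThresholdVector",
  representation(task = "character", values = "numeric", nSteps = "integer")
)

setValidity("ThresholdVector", function(object) {
  msg <- character()
  if (length(object@values) != 6L)
    msg <- c(msg, "'values' must have length 6")
  if (object@nSteps < 2L || object@nSteps > 5L)
    msg <- c(msg, "'nSteps' must lie in 2..5")
  if (length(msg)) msg else TRUE
})

#' ActivationSequence: ordinal muscular activation sequence
#'
#' Length-6 vector of channel indices ranked by the time each channel first
#' exceeded its high threshold inside the transient window; channels that
#' never crossed are encoded 0 and occupy the trailing positions.
#'
#' @slot entries Integer length 6 in 0..6; non-zero entries are distinct.
#' @slot crossingTimesMs Named numeric: absolute crossing time (ms) of each
#'   crossed channel, ascending.
#'
#' @export
setClass("ActivationSequence",
  representation(entries = "integer", crossingTimesMs = "numeric")
)

setValidity("ActivationSequence", function(object) {
  msg <- character()
  e <- object@entries
  if (length(e) != 6L || any(e < 0L) || any(e > 6L))
    msg <- c(msg, "'entries' must be 6 integers in 0..6")
  nz <- e[e > 0L]
  if (anyDuplicated(nz))
    msg <- c(msg, "non-zero entries must be distinct channels")
  if (length(nz) && any(e[seq_along(nz)] == 0L))
    msg <- c(msg, "zeros may only occupy trailing positions")
  ct <- object@crossingTimesMs
  if (length(ct) != length(nz))
    msg <- c(msg, "one crossing time per crossed channel is required")
  else if (length(ct)) {
    if (is.null(names(ct)) || !identical(as.integer(names(ct)), nz))
      msg <- c(msg, "crossing times must be named by channel, in rank order")
    if (is.unsorted(ct))
      msg <- c(msg, "crossing times must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureTable: per-acquisition feature rows of one kind
#'
#' A set of feature vectors of a single kind: the refined 12-element
#' sequence feature (\code{"sequence12"}), binned transient envelopes
#' (\code{"ets"}), or steady-state mean-absolute-value features
#' (\code{"ess"}).
#'
#' @slot ids Recording identifiers.
#' @slot labels Gesture labels.
#' @slot features Numeric matrix, one row per recording.
#' @slot kind One of "sequence12", "ets", "ess".
#'
#' @export
setClass("FeatureTable",
  representation(ids = "character", labels = "character",
                 features = "matrix", kind = "character")
)

setValidity("FeatureTable", function(object) {
  msg <- character()
  n <- nrow(object@features)
  if (length(object@ids) != n || length(object@labels) != n)
    msg <- c(msg, "'ids' and 'labels' must match the feature rows")
  if (!(object@kind %in% c("sequence12", "ets", "ess")))
    msg <- c(msg, "'kind' must be sequence12, ets or ess")
  if (n > 0L) {
    f <- object@features
    if (object@kind == "sequence12") {
      if (ncol(f) != 12L)
        msg <- c(msg, "sequence12 features must have 12 entries")
      else if (any(f != round(f)) || any(f < 0) || any(f > 6))
        msg <- c(msg, "sequence12 entries must be integers in 0..6")
    } else if (object@kind == "ess") {
      if (ncol(f) != 6L || any(f < 0))
        msg <- c(msg, "ess features must be 6 non-negative values")
    } else if (any(f < 0)) {
      msg <- c(msg, "ets features must be non-negative")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GestureClassifier: a trained gesture classifier
#'
#' Wraps a fitted model of one of the four supported kinds together with the
#' feature kind it was trained on, the class labels, and any fitting notes
#' (e.g. the regularisation fallback of the one-vs-all LDA).
#'
#' @slot kind One of "nlr", "svm", "ann", "lda".
#' @slot featureKind Feature kind the model consumes.
#' @slot classes Class labels, in fitting order.
#' @slot fit Kind-specific fitted object(s).
#' @slot seed Seed used for any stochastic part of training.
#' @slot notes Character vector of fitting notes.
#'
#' @export
setClass("GestureClassifier",
  representation(kind = "character", featureKind = "character",
                 classes = "character", fit = "list", seed = "numeric",
                 notes = "character")
)

setValidity("GestureClassifier", function(object) {
  msg <- character()
  if (!(object@kind %in% c("nlr", "svm", "ann", "lda")))
    msg <- c(msg, "'kind' must be nlr, svm, ann or lda")
  if (length(object@classes) < 2L)
    msg <- c(msg, "at least two classes are required")
  if (length(msg)) msg else TRUE
})
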