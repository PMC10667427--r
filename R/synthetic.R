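## Synthetic EMG-envelope generator.
##
## Emulates 4-s, 6-channel, 1 kHz envelope acquisitions that start from rest:
## correlated rest noise on every channel, a logistic rise to plateau on the
## recruited channels with per-repetition delay jitter, a slow within-trial
## contraction profile (ramp up, then relaxation toward the trial end), and
## slow multiplicative plateau jitter. Ground truth (movement onset, realised
## activation order, active channels) is stored on every recording.

#' Construct a gesture profile
#'
#' @param name Gesture label.
#' @param order Activation order: channel indices (1..6), first to activate
#'   first. Empty for the Rest profile.
#' @param meanDelays Mean activation delay (ms) after movement onset for each
#'   channel in \code{order}; non-decreasing.
#' @param plateauAmplitudes Either a length-6 vector of plateau amplitudes
#'   (V, zero on inactive channels) or a vector aligned with \code{order}.
#' @param delayJitterSd Per-repetition delay jitter sd (ms).
#' @param amplitudeJitterCv Coefficient of variation of the slow
#'   multiplicative plateau jitter.
#' @param riseTime 10--90\% rise time (ms).
#' @return A \linkS4class{GestureProfile}.
#' @export
gestureProfile <- function(name, order = integer(), meanDelays = numeric(),
                           plateauAmplitudes = numeric(),
                           delayJitterSd = 10, amplitudeJitterCv = 0.05,
                           riseTime = 100) {
  order <- as.integer(order)
  if (length(plateauAmplitudes) == length(order) &&
      length(plateauAmplitudes) != 6L) {
    amp <- numeric(6)
    amp[order] <- plateauAmplitudes
    plateauAmplitudes <- amp
  }
  if (!length(plateauAmplitudes)) plateauAmplitudes <- numeric(6)
  new("GestureProfile", name = name, activeChannels = sort(order),
      order = order, meanDelays = as.numeric(meanDelays),
      delayJitterSd = delayJitterSd,
      plateauAmplitudes = as.numeric(plateauAmplitudes),
      amplitudeJitterCv = amplitudeJitterCv, riseTime = riseTime)
}

#' @rdname gestureProfile
#' @export
restProfile <- function() gestureProfile(REST_LABEL)

#' Construct a rest-noise model
#'
#' @param restMean Mean rest amplitude (V).
#' @param restSd Rest amplitude standard deviation (V).
#' @param correlationTime Autocorrelation time constant (ms).
#' @return A \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(restMean = 0.012, restSd = 0.0007,
                       correlationTime = 20) {
  new("NoiseModel", restMean = restMean, restSd = restSd,
      correlationTime = correlationTime)
}

#' @rdname noiseModel
#' @export
defaultNoiseModel <- function() noiseModel()

#' Default gesture profiles of the simulator
#'
#' Four gestures with distinct recruitment orders and recruitment counts
#' (between two and five active channels), plus optionally the Rest profile.
#' Delays are spaced 60--80 ms apart so the first three activations fall well
#' inside a 300 ms transient window; the channel that produces the final
#' partial-sequence activation carries the largest plateau amplitude, so the
#' steady-state peak always follows the transient activations.
#'
#' @param includeRest Append the Rest profile.
#' @return Named list of \linkS4class{GestureProfile} objects.
#' @export
defaultProfiles <- function(includeRest = FALSE) {
  amp <- function(order, values) {
    a <- numeric(6)
    a[order] <- values
    a
  }
  p <- list(
    Spherical = gestureProfile("Spherical", order = c(4L, 1L, 3L, 5L, 2L),
      meanDelays = c(0, 60, 120, 180, 240),
      plateauAmplitudes = amp(c(4, 1, 3, 5, 2), c(1.0, 0.9, 1.5, 0.8, 0.7))),
    Tip = gestureProfile("Tip", order = c(2L, 6L, 1L),
      meanDelays = c(0, 70, 140),
      plateauAmplitudes = amp(c(2, 6, 1), c(1.0, 0.9, 1.5))),
    Platform = gestureProfile("Platform", order = c(6L, 3L, 2L, 5L),
      meanDelays = c(0, 65, 130, 195),
      plateauAmplitudes = amp(c(6, 3, 2, 5), c(1.0, 0.9, 1.5, 0.8))),
    Point = gestureProfile("Point", order = c(5L, 4L),
      meanDelays = c(0, 80),
      plateauAmplitudes = amp(c(5, 4), c(1.0, 1.4)))
  )
  if (includeRest) p$Rest <- restProfile()
  p
}

## AR(1) noise with stationary sd `sd` and correlation time `tauMs`
.arNoise <- function(n, sd, tauMs, fs) {
  if (sd <= 0) return(numeric(n))
  if (tauMs <= 0) return(stats::rnorm(n, 0, sd))
  rho <- exp(-(1000 / fs) / tauMs)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

## normalised logistic rise: exactly 0 at u <= 0, ~1 at u >= riseTime * 1.5
.riseShape <- function(u, riseTime) {
  tau <- riseTime / (2 * log(9))   # 10-90% definition
  s0 <- 1 / (1 + exp(riseTime / (2 * tau)))
  s <- 1 / (1 + exp(-(u - riseTime / 2) / tau))
  pmax(0, (s - s0) / (1 - s0))
}

## slow within-trial contraction profile shared by all channels:
## 1 during the transient, ramp to `peak` at 0.8 T, relax to `end` at T
.contractionProfile <- function(tMs, durMs, peak = 1.2, end = 0.85) {
  rampFrom <- 0.3 * durMs
  rampTo <- 0.8 * durMs
  out <- rep(1, length(tMs))
  up <- tMs > rampFrom & tMs <= rampTo
  out[up] <- 1 + (peak - 1) * (tMs[up] - rampFrom) / (rampTo - rampFrom)
  dn <- tMs > rampTo
  out[dn] <- peak + (end - peak) * (tMs[dn] - rampTo) / (durMs - rampTo)
  out
}

#' Generate one synthetic envelope recording
#'
#' Movement onset is drawn uniformly in [restMs, restMs + 200] ms; each
#' active channel starts its logistic rise at onset + (jittered) delay.
#' The ground truth stored on the recording holds the realised movement
#' onset, activation order (by realised delay), active channels and
#' per-channel activation start times.
#'
#' @param profile A \linkS4class{GestureProfile}.
#' @param noise A \linkS4class{NoiseModel}.
#' @param seed Integer seed; the recording is a deterministic function of
#'   (profile, noise, seed).
#' @param fs Sampling frequency (Hz).
#' @param durationMs Acquisition length (ms).
#' @param restMs Guaranteed initial rest span (ms).
#' @param subjectId Subject identifier.
#' @return An \linkS4class{EnvelopeRecording}.
#' @export
generateRecording <- function(profile, noise, seed, fs = 1000,
                              durationMs = 4000, restMs = 500,
                              subjectId = "S1") {
  validObject(profile)
  validObject(noise)
  k <- length(profile@order)
  maxDelay <- if (k) max(profile@meanDelays) else 0
  if (k && restMs + 200 + maxDelay + profile@riseTime > durationMs)
    stop("activation does not fit: rest + onset span + max delay + rise time ",
         "exceeds the acquisition duration")
  set.seed(as.integer(seed %% 2147483647))
  n <- round(durationMs * fs / 1000)
  tMs <- (seq_len(n) - 1) * 1000 / fs
  x <- matrix(0, n, 6)
  truth <- list(onsetMs = NA_real_, order = integer(),
                activeChannels = integer(), startTimesMs = numeric())
  if (k) {
    onset <- stats::runif(1, restMs, restMs + 200)
    delays <- pmax(0, profile@meanDelays +
                     stats::rnorm(k, 0, profile@delayJitterSd))
    starts <- onset + delays
    ordReal <- profile@order[order(delays, seq_len(k))]
    m <- .contractionProfile(tMs, durationMs)
    for (i in seq_len(k)) {
      ch <- profile@order[i]
      shape <- .riseShape(tMs - starts[i], profile@riseTime)
      jit <- if (profile@amplitudeJitterCv > 0)
        1 + .arNoise(n, profile@amplitudeJitterCv, 300, fs) else 1
      x[, ch] <- profile@plateauAmplitudes[ch] * shape * m * pmax(0, jit)
    }
    st <- starts
    names(st) <- as.character(profile@order)
    truth <- list(onsetMs = min(starts), order = ordReal,
                  activeChannels = profile@activeChannels, startTimesMs = st)
  }
  for (ch in 1:6)
    x[, ch] <- x[, ch] + noise@restMean +
      .arNoise(n, noise@restSd, noise@correlationTime, fs)
  x <- pmin(pmax(x, 0), FULL_SCALE)
  envelopeRecording(x, fs = fs, label = profile@name, subjectId = subjectId,
                    truth = truth)
}

#' Generate a labelled synthetic dataset
#'
#' Per-recording seeds are derived reproducibly from the master seed, so the
#' dataset is a deterministic function of (profiles, noise, seed).
#'
#' @param profiles List of \linkS4class{GestureProfile} objects with distinct
#'   names (include \code{restProfile()} for Rest acquisitions).
#' @param noise A \linkS4class{NoiseModel}.
#' @param repsPerGesture Repetitions per profile (>= 1).
#' @param seed Master integer seed.
#' @param subjectId Subject identifier.
#' @param ... Passed to \code{\link{generateRecording}}.
#' @return Named list of \linkS4class{EnvelopeRecording} objects
#'   (\code{subject_label_rep}).
#' @export
generateDataset <- function(profiles, noise, repsPerGesture, seed,
                            subjectId = "S1", ...) {
  if (repsPerGesture < 1) stop("'repsPerGesture' must be >= 1")
  nm <- vapply(profiles, function(p) p@name, character(1))
  if (anyDuplicated(nm)) stop("duplicate gesture names in 'profiles'")
  nTot <- length(profiles) * repsPerGesture
  seeds <- .deriveSeeds(seed, nTot)
  recs <- vector("list", nTot)
  ids <- character(nTot)
  idx <- 0L
  for (p in profiles) {
    for (r in seq_len(repsPerGesture)) {
      idx <- idx + 1L
      recs[[idx]] <- generateRecording(p, noise, seeds[idx],
                                       subjectId = subjectId, ...)
      ids[idx] <- sprintf("%s_%s_%03d", subjectId, p@name, r)
    }
  }
  names(recs) <- ids
  recs
}
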