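## Sequence encoding: one acquisition -> ordinal muscular activation
## sequence under a threshold vector, and the refined 12-element
## classification feature (four task-specific partial sequences,
## concatenated).

#' Encode the muscular activation sequence of one acquisition
#'
#' Channels are ranked by the first sample exceeding their high threshold
#' inside the transient window from the Start of Activation. Channels that
#' never cross (or whose threshold is the sentinel) are encoded 0 at the
#' tail. Simultaneous crossings are broken toward the lower channel index.
#'
#' @param rec An \linkS4class{EnvelopeRecording}.
#' @param soaMs Start of Activation (ms).
#' @param thVector A \linkS4class{ThresholdVector} (or numeric length 6).
#' @param windowMs Transient window length (ms).
#' @return An \linkS4class{ActivationSequence}.
#' @export
encodeSequence <- function(rec, soaMs, thVector, windowMs = 300) {
  if (is.na(soaMs)) stop("'soaMs' must be present to encode a sequence")
  values <- if (is(thVector, "ThresholdVector")) thresholdValues(thVector)
            else as.numeric(thVector)
  if (length(values) != 6L) stop("a threshold per channel is required")
  fs <- sampleRate(rec)
  x <- samples(rec)
  rows <- .windowRows(soaMs, soaMs + windowMs, fs, nrow(x),
                      "transient window")
  times <- rep(Inf, 6)
  for (ch in 1:6) {
    if (.isSentinel(values[ch])) next
    idx <- which(x[rows, ch] > values[ch])
    if (length(idx)) times[ch] <- .rowToMs(rows[idx[1]], fs)
  }
  crossed <- which(is.finite(times))
  ord <- crossed[order(times[crossed], crossed)]
  entries <- integer(6)
  entries[seq_along(ord)] <- ord
  ct <- times[ord]
  names(ct) <- as.character(ord)
  new("ActivationSequence", entries = entries, crossingTimesMs = ct)
}

#' Refined 12-element classification feature of one acquisition
#'
#' The acquisition is encoded under each of the four task-representative
#' threshold vectors (fixed task order), each sequence is truncated to its
#' first three elements, and the four partial sequences are concatenated
#' row-wise into a single 12-element vector.
#'
#' @param rec An \linkS4class{EnvelopeRecording}.
#' @param soaMs Start of Activation (ms).
#' @param vectors Named list of the four task
#'   \linkS4class{ThresholdVector}s.
#' @param windowMs Transient window length (ms).
#' @param keep Elements kept per task sequence (3).
#' @return Integer vector of length \code{4 * keep} (12).
#' @export
encodeFeatures <- function(rec, soaMs, vectors, windowMs = 300, keep = 3L) {
  if (!all(GESTURE_TASKS %in% names(vectors)))
    stop("a threshold vector for each task (",
         paste(GESTURE_TASKS, collapse = ", "), ") is required")
  out <- unlist(lapply(GESTURE_TASKS, function(task) {
    sequenceEntries(encodeSequence(rec, soaMs, vectors[[task]],
                                   windowMs))[seq_len(keep)]
  }))
  names(out) <- paste0(rep(GESTURE_TASKS, each = keep), "_",
                       rep(seq_len(keep), 4))
  out
}

#' Build the sequence-feature table of a dataset
#'
#' @param recordings Named list of acquisitions.
#' @param annotations Matching \linkS4class{OnsetAnnotation} list.
#' @param vectors Named list of the four task threshold vectors.
#' @param windowMs Transient window length (ms).
#' @return A \linkS4class{FeatureTable} of kind \code{"sequence12"};
#'   acquisitions without a detected SoA are omitted.
#' @export
sequenceFeatureTable <- function(recordings, annotations, vectors,
                                 windowMs = 300) {
  keep <- !vapply(annotations, function(a) is.na(soaMs(a)), logical(1))
  rows <- lapply(which(keep), function(i)
    encodeFeatures(recordings[[i]], soaMs(annotations[[i]]), vectors,
                   windowMs))
  f <- do.call(rbind, rows)
  ids <- names(recordings)[keep] %||% sprintf("rec_%03d", which(keep))
  featureTable(f, vapply(recordings[keep], recLabel, character(1)),
               ids, kind = "sequence12")
}

#' Activation timing and entity summary
#'
#' Mean latency from the Start of Activation of the first \code{k}
#' activations across acquisitions, the mean number of activations inside
#' the transient window ("activation timing"), and the mean number of
#' active channels ("activation entity").
#'
#' @param sequences List of \linkS4class{ActivationSequence} objects.
#' @param soaMs Start of Activation (ms) of each acquisition.
#' @param annotations Optional \linkS4class{OnsetAnnotation} list; when
#'   given, the activation entity counts low-threshold-active channels,
#'   otherwise channels that crossed their high threshold.
#' @param k Number of leading activations summarised.
#' @return List with \code{meanLatenciesMs} (length \code{k}),
#'   \code{meanActivations}, \code{meanActiveChannels}, \code{n}.
#' @export
activationTimingSummary <- function(sequences, soaMs, annotations = NULL,
                                    k = 3L) {
  if (!length(sequences)) stop("no sequences to summarise")
  if (length(sequences) != length(soaMs))
    stop("one SoA per sequence is required")
  lat <- do.call(rbind, lapply(seq_along(sequences), function(i) {
    ct <- unname(crossingTimes(sequences[[i]])) - soaMs[i]
    c(ct, rep(NA_real_, k))[seq_len(k)]
  }))
  nAct <- vapply(sequences, function(s) sum(sequenceEntries(s) > 0L),
                 numeric(1))
  entity <- if (is.null(annotations)) mean(nAct) else
    mean(vapply(annotations, function(a) sum(activeFlags(a)), numeric(1)))
  list(meanLatenciesMs = colMeans(lat, na.rm = TRUE),
       meanActivations = mean(nAct),
       meanActiveChannels = entity,
       n = length(sequences))
}
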