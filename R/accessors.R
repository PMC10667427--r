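## Accessors, constructors for simple value classes, and show methods.

#' @rdname EnvelopeRecording-class
#' @export
setMethod("samples", "EnvelopeRecording", function(object) object@samples)

#' @rdname EnvelopeRecording-class
#' @export
setMethod("sampleRate", "EnvelopeRecording", function(object) object@fs)

#' @rdname EnvelopeRecording-class
#' @export
setMethod("recLabel", "EnvelopeRecording", function(object) object@label)

#' @rdname EnvelopeRecording-class
#' @export
setMethod("subjectId", "EnvelopeRecording", function(object) object@subjectId)

#' @rdname EnvelopeRecording-class
#' @export
setMethod("truthInfo", "EnvelopeRecording", function(object) object@truth)

#' @rdname EnvelopeRecording-class
#' @export
setMethod("durationMs", "EnvelopeRecording",
          function(object) nrow(object@samples) * 1000 / object@fs)

#' Construct an envelope recording
#'
#' @param samples Time-by-6 numeric matrix of envelope voltages.
#' @param fs Sampling frequency (Hz).
#' @param label Gesture label.
#' @param subjectId Subject identifier.
#' @param truth Optional ground-truth list.
#' @return An \linkS4class{EnvelopeRecording}.
#' @export
envelopeRecording <- function(samples, fs = 1000, label = REST_LABEL,
                              subjectId = "S1", truth = list()) {
  colnames(samples) <- paste0("emg", 1:6)
  new("EnvelopeRecording", samples = samples, fs = fs, label = label,
      subjectId = subjectId, truth = truth)
}

#' Construct a rest model from its statistics
#'
#' @param mu,sigma Rest mean and standard deviation (V).
#' @param x Threshold multiplier.
#' @return A \linkS4class{RestModel} with \code{thLow = mu + x * sigma}.
#' @export
restModel <- function(mu, sigma, x) {
  .assertScalarNumber(mu, "mu")
  .assertScalarNumber(sigma, "sigma")
  .assertScalarNumber(x, "x")
  new("RestModel", mu = mu, sigma = sigma, x = x, thLow = mu + x * sigma)
}

#' @rdname RestModel-class
#' @export
setMethod("thLow", "RestModel", function(object) object@thLow)

#' @rdname OnsetAnnotation-class
#' @export
setMethod("soaMs", "OnsetAnnotation", function(object) object@soaMs)

#' @rdname OnsetAnnotation-class
#' @export
setMethod("activeFlags", "OnsetAnnotation", function(object) object@activeFlags)

#' @rdname OnsetAnnotation-class
#' @export
setMethod("firstCrossingMs", "OnsetAnnotation",
          function(object) object@firstCrossingMs)

#' @rdname ThresholdVector-class
#' @export
setMethod("thresholdValues", "ThresholdVector",
          function(object) object@values)

#' @rdname ThresholdVector-class
#' @export
setMethod("taskName", "ThresholdVector", function(object) object@task)

#' @rdname ActivationSequence-class
#' @export
setMethod("sequenceEntries", "ActivationSequence",
          function(object) object@entries)

#' @rdname ActivationSequence-class
#' @export
setMethod("crossingTimes", "ActivationSequence",
          function(object) object@crossingTimesMs)

#' @rdname FeatureTable-class
#' @export
setMethod("featureKind", "FeatureTable", function(object) object@kind)

#' @rdname FeatureTable-class
#' @export
setMethod("featureMatrix", "FeatureTable", function(object) object@features)

#' @rdname FeatureTable-class
#' @export
setMethod("recordingIds", "FeatureTable", function(object) object@ids)

#' @rdname FeatureTable-class
#' @export
setMethod("gestureLabels", "FeatureTable", function(object) object@labels)

#' Construct a feature table
#'
#' @param features Numeric matrix, one row per recording.
#' @param labels Gesture labels, one per row.
#' @param ids Recording identifiers; defaults to rec_001, ...
#' @param kind Feature kind: "sequence12", "ets" or "ess".
#' @return A \linkS4class{FeatureTable}.
#' @export
featureTable <- function(features, labels, ids = NULL, kind = "sequence12") {
  features <- as.matrix(features)
  if (is.null(ids)) ids <- sprintf("rec_%03d", seq_len(nrow(features)))
  new("FeatureTable", ids = as.character(ids), labels = as.character(labels),
      features = features, kind = kind)
}

#' @rdname FeatureTable-class
#' @param i Row indices.
#' @param j,drop,... Ignored (rows only).
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  new("FeatureTable", ids = x@ids[i], labels = x@labels[i],
      features = x@features[i, , drop = FALSE], kind = x@kind)
})

#' @rdname FeatureTable-class
#' @export
setMethod("nrow", "FeatureTable", function(x) nrow(x@features))

setMethod("show", "EnvelopeRecording", function(object) {
  tr <- if (length(object@truth)) " (with ground truth)" else ""
  cat(sprintf(
    "EnvelopeRecording '%s' [%s]: %d samples x 6 channels @ %g Hz (%.2f s)%s\n",
    object@label, object@subjectId, nrow(object@samples), object@fs,
    nrow(object@samples) / object@fs, tr))
})

setMethod("show", "RestModel", function(object) {
  cat(sprintf("RestModel: mu = %.6g V, sigma = %.6g V, x = %g -> TH_Low = %.6g V\n",
              object@mu, object@sigma, object@x, object@thLow))
})

setMethod("show", "OnsetAnnotation", function(object) {
  soa <- if (is.na(object@soaMs)) "none (Rest)" else
    sprintf("%.0f ms", object@soaMs)
  cat(sprintf("OnsetAnnotation: SoA = %s; active channels: %s\n", soa,
              if (any(object@activeFlags))
                paste(which(object@activeFlags), collapse = ", ")
              else "none"))
})

setMethod("show", "ThresholdVector", function(object) {
  v <- ifelse(.isSentinel(object@values), "NA",
              sprintf("%.4f", object@values))
  cat(sprintf("ThresholdVector [%s, #step = %d]: %s\n", object@task,
              object@nSteps, paste(v, collapse = " ")))
})

setMethod("show", "ActivationSequence", function(object) {
  cat(sprintf("ActivationSequence: (%s)\n",
              paste(object@entries, collapse = ", ")))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable [%s]: %d recordings x %d features (%s)\n",
              object@kind, nrow(object@features), ncol(object@features),
              paste(unique(object@labels), collapse = ", ")))
})

setMethod("show", "GestureClassifier", function(object) {
  cat(sprintf("GestureClassifier [%s on %s]: classes %s\n",
              toupper(object@kind), object@featureKind,
              paste(object@classes, collapse = ", ")))
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})
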