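## Generics for accessors. Slot access from user code goes through these.

#' @rdname EnvelopeRecording-class
#' @param object,x An object.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname EnvelopeRecording-class
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname EnvelopeRecording-class
#' @export
setGeneric("recLabel", function(object) standardGeneric("recLabel"))

#' @rdname EnvelopeRecording-class
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname EnvelopeRecording-class
#' @export
setGeneric("truthInfo", function(object) standardGeneric("truthInfo"))

#' @rdname EnvelopeRecording-class
#' @export
setGeneric("durationMs", function(object) standardGeneric("durationMs"))

#' @rdname RestModel-class
#' @param object An object.
#' @export
setGeneric("thLow", function(object) standardGeneric("thLow"))

#' @rdname OnsetAnnotation-class
#' @param object An object.
#' @export
setGeneric("soaMs", function(object) standardGeneric("soaMs"))

#' @rdname OnsetAnnotation-class
#' @export
setGeneric("activeFlags", function(object) standardGeneric("activeFlags"))

#' @rdname OnsetAnnotation-class
#' @export
setGeneric("firstCrossingMs",
           function(object) standardGeneric("firstCrossingMs"))

#' @rdname ThresholdVector-class
#' @param object An object.
#' @export
setGeneric("thresholdValues",
           function(object) standardGeneric("thresholdValues"))

#' @rdname ThresholdVector-class
#' @export
setGeneric("taskName", function(object) standardGeneric("taskName"))

#' @rdname ActivationSequence-class
#' @param object An object.
#' @export
setGeneric("sequenceEntries",
           function(object) standardGeneric("sequenceEntries"))

#' @rdname ActivationSequence-class
#' @export
setGeneric("crossingTimes", function(object) standardGeneric("crossingTimes"))

#' @rdname FeatureTable-class
#' @param object An object.
#' @export
setGeneric("featureKind", function(object) standardGeneric("featureKind"))

#' @rdname FeatureTable-class
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname FeatureTable-class
#' @export
setGeneric("recordingIds", function(object) standardGeneric("recordingIds"))

#' @rdname FeatureTable-class
#' @export
setGeneric("gestureLabels", function(object) standardGeneric("gestureLabels"))

#' Classify feature rows with a trained model
#'
#' @param model A \linkS4class{GestureClassifier}.
#' @param newdata A \linkS4class{FeatureTable} of the model's feature kind,
#'   or a bare numeric matrix with matching columns.
#' @return Character vector of predicted gesture labels.
#' @export
setGeneric("classify", function(model, newdata) standardGeneric("classify"))
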