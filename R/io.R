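## Plain-text IO: recordings as CSV, dataset manifests as JSON, feature
## tables as TSV. Readers validate and reject malformed input rather than
## coerce; writers are deterministic. Voltages are stored with 6 decimal
## digits, below the sensor noise floor.

#' Write / read one envelope recording as CSV
#'
#' The CSV has columns \code{time_ms, emg1..emg6}, one row per sample.
#'
#' @param rec An \linkS4class{EnvelopeRecording}.
#' @param path File path.
#' @return \code{writeRecordingCsv} returns \code{path} invisibly;
#'   \code{readRecordingCsv} returns an \linkS4class{EnvelopeRecording}.
#' @export
writeRecordingCsv <- function(rec, path) {
  x <- samples(rec)
  df <- data.frame(time_ms = .rowToMs(seq_len(nrow(x)), sampleRate(rec)))
  for (ch in 1:6) df[[paste0("emg", ch)]] <- sprintf("%.6f", x[, ch])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRecordingCsv
#' @param label,subjectId,truth Metadata attached to the loaded recording
#'   (normally taken from the dataset manifest).
#' @export
readRecordingCsv <- function(path, label = REST_LABEL, subjectId = "S1",
                             truth = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- c("time_ms", paste0("emg", 1:6))
  if (!identical(names(df), expected))
    stop("recording CSV must have columns ", paste(expected, collapse = ", "),
         "; got ", paste(names(df), collapse = ", "))
  t <- df$time_ms
  if (anyNA(t) || any(diff(t) <= 0))
    stop("non-monotone or missing time axis at row ",
         which(c(FALSE, diff(t) <= 0) | is.na(t))[1])
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6) stop("time axis must be uniformly sampled")
  fs <- 1000 / dt[1]
  x <- as.matrix(df[, -1])
  if (anyNA(x) || any(x < 0) || any(x > FULL_SCALE)) {
    bad <- which(is.na(x) | x < 0 | x > FULL_SCALE, arr.ind = TRUE)
    stop(sprintf("voltage out of [0, %g] V at row %d", FULL_SCALE, bad[1, 1]))
  }
  envelopeRecording(x, fs = fs, label = label, subjectId = subjectId,
                    truth = truth)
}

#' Write / read a dataset directory (recordings + JSON manifest)
#'
#' Each recording is written as \code{<id>.csv} and a \code{manifest.json}
#' records subject, sampling rate, labels, ground truth and the generation
#' seed (if supplied).
#'
#' @param recs Named list of \linkS4class{EnvelopeRecording} objects.
#' @param dir Dataset directory (created if missing).
#' @param seed Optional generation seed recorded in the manifest.
#' @return \code{writeDataset} returns \code{dir} invisibly;
#'   \code{readDataset} returns the named list of recordings.
#' @export
writeDataset <- function(recs, dir, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(recs) %||% sprintf("rec_%03d", seq_along(recs))
  entries <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    path <- paste0(ids[i], ".csv")
    writeRecordingCsv(recs[[i]], file.path(dir, path))
    tr <- truthInfo(recs[[i]])
    entries[[i]] <- list(path = path, label = recLabel(recs[[i]]),
                         truth = if (length(tr)) tr else NULL)
  }
  manifest <- list(subject_id = subjectId(recs[[1]]),
                   fs = sampleRate(recs[[1]]),
                   created_with_seed = seed, recordings = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  recs <- list()
  for (e in manifest$recordings) {
    p <- file.path(dir, e$path)
    if (!file.exists(p)) stop("manifest references missing file ", e$path)
    truth <- e$truth
    if (!is.null(truth)) {
      truth$onsetMs <- truth$onsetMs %||% NA_real_
      truth$order <- as.integer(unlist(truth$order))
      truth$activeChannels <- as.integer(unlist(truth$activeChannels))
      st <- unlist(truth$startTimesMs)
      truth$startTimesMs <- if (is.null(st)) numeric() else st
    } else truth <- list()
    rec <- readRecordingCsv(p, label = e$label,
                            subjectId = manifest$subject_id, truth = truth)
    if (abs(sampleRate(rec) - manifest$fs) > 1e-6)
      stop("sampling rate of ", e$path, " disagrees with the manifest")
    recs[[sub("\\.csv$", "", e$path)]] <- rec
  }
  recs
}

#' Write / read a feature table as TSV
#'
#' Columns are \code{recording_id, label, feature_kind, f1..fk}; the feature
#' kind must be constant across rows and sequence-feature entries stay
#' integer through a round trip.
#'
#' @param table A \linkS4class{FeatureTable}.
#' @param path File path.
#' @return \code{writeFeatureTable} returns \code{path} invisibly;
#'   \code{readFeatureTable} returns a \linkS4class{FeatureTable}.
#' @export
writeFeatureTable <- function(table, path) {
  validObject(table)
  f <- featureMatrix(table)
  df <- data.frame(recording_id = recordingIds(table),
                   label = gestureLabels(table),
                   feature_kind = rep(featureKind(table), nrow(f)))
  for (j in seq_len(ncol(f)))
    df[[paste0("f", j)]] <- if (featureKind(table) == "sequence12")
      as.integer(f[, j]) else f[, j]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  fixed <- c("recording_id", "label", "feature_kind")
  if (length(df) < length(fixed) || !identical(names(df)[1:3], fixed))
    stop("feature table must start with columns ",
         paste(fixed, collapse = ", "))
  if (nrow(df) == 0L) {
    k <- length(df) - 3L
    return(featureTable(matrix(numeric(), 0L, k), character(), character(),
                        kind = "sequence12"))
  }
  kind <- unique(df$feature_kind)
  if (length(kind) != 1L)
    stop("mixed feature kinds in one table: ", paste(kind, collapse = ", "))
  f <- as.matrix(df[, -(1:3), drop = FALSE])
  if (!is.numeric(f) || anyNA(f)) stop("non-numeric feature entries")
  featureTable(f, df$label, df$recording_id, kind = kind)
}
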