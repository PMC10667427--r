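## High-threshold ladders and the exhaustive combinatorial search for the
## representative per-task threshold vector.
##
## The search enumerates one candidate per channel (#step^#EMG combinations),
## encodes the activation sequence of every acquisition under each
## combination, and keeps the combination whose modal sequence is most
## repeated. Crossing times are precomputed per acquisition as a
## channel-by-candidate matrix, and sequences are compared as base-7 integer
## keys, so the enumeration is vectorised over combinations.

#' Initial maximum high-threshold vector of a task
#'
#' Per channel, 80\% of the envelope peak within a 300 ms window from the
#' Start of Activation, averaged over the acquisitions in which the channel
#' is active. Channels active in no acquisition get the \code{NA_VALUE}
#' sentinel.
#'
#' @param recordings Acquisitions of one task.
#' @param annotations Matching \linkS4class{OnsetAnnotation} list.
#' @param windowMs Transient window length (ms) from the SoA.
#' @param peakFraction Fraction of the in-window peak used as the starting
#'   threshold.
#' @return Numeric length 6 (V, possibly sentinel).
#' @export
initialMaxThreshold <- function(recordings, annotations, windowMs = 300,
                                peakFraction = 0.8) {
  if (length(recordings) != length(annotations))
    stop("one annotation per recording is required")
  withSoa <- !vapply(annotations, function(a) is.na(soaMs(a)), logical(1))
  if (!any(withSoa)) stop("no acquisition with a detected SoA")
  out <- rep(NA_VALUE, 6)
  for (ch in 1:6) {
    vals <- numeric()
    for (i in which(withSoa)) {
      if (!activeFlags(annotations[[i]])[ch]) next
      rec <- recordings[[i]]
      rows <- .windowRows(soaMs(annotations[[i]]),
                          soaMs(annotations[[i]]) + windowMs,
                          sampleRate(rec), nrow(samples(rec)),
                          "transient window")
      vals <- c(vals, peakFraction * max(samples(rec)[rows, ch]))
    }
    if (length(vals)) out[ch] <- mean(vals)
  }
  out
}

#' Build a descending threshold ladder for one channel
#'
#' Candidates are \code{maxTh * 0.9^i} for \code{i = 0..nSteps-1}; a
#' candidate at or below the low threshold becomes the sentinel, and a
#' sentinel starting value yields an all-sentinel ladder. The 50\%-of-peak
#' floor of the decrement scheme caps the ladder at 5 steps.
#'
#' @param maxTh Starting threshold (V) or the sentinel.
#' @param thLow Low threshold (V).
#' @param nSteps Ladder depth, 2..5.
#' @param channel Channel index.
#' @return A \linkS4class{ThresholdLadder}.
#' @export
buildLadder <- function(maxTh, thLow, nSteps, channel = 1L) {
  nSteps <- as.integer(nSteps)
  if (is.na(nSteps) || nSteps < 2L || nSteps > 5L)
    stop("'nSteps' must lie in 2..5 (the ladder admits at most 5 steps)")
  values <- if (.isSentinel(maxTh) || maxTh <= thLow) {
    rep(NA_VALUE, nSteps)
  } else {
    v <- maxTh * 0.9^(seq_len(nSteps) - 1)
    v[v <= thLow] <- NA_VALUE
    v
  }
  new("ThresholdLadder", channel = as.integer(channel), values = values,
      nSteps = nSteps)
}

## channel x candidate matrix of first-crossing times (absolute ms, Inf when
## the candidate is never exceeded in [soa, soa + windowMs))
.crossingTimeMatrix <- function(rec, soa, ladderValues, windowMs) {
  fs <- sampleRate(rec)
  x <- samples(rec)
  rows <- .windowRows(soa, soa + windowMs, fs, nrow(x), "transient window")
  nSteps <- length(ladderValues[[1]])
  ct <- matrix(Inf, 6, nSteps)
  for (ch in 1:6) {
    xw <- x[rows, ch]
    for (s in seq_len(nSteps)) {
      v <- ladderValues[[ch]][s]
      if (.isSentinel(v)) next
      idx <- which(xw > v)
      if (length(idx)) ct[ch, s] <- .rowToMs(rows[idx[1]], fs)
    }
  }
  ct
}

## base-7 sequence keys for a K x 6 matrix of crossing times: channel j gets
## rank 1 + #{channels crossing earlier (ties to the lower index)}, and the
## key digit at its rank position; non-crossing channels contribute trailing
## zeros implicitly.
.sequenceKeys <- function(Tm) {
  K <- nrow(Tm)
  fin <- is.finite(Tm)
  key <- numeric(K)
  for (j in 1:6) {
    tj <- Tm[, j]
    r <- rep(1L, K)
    for (k in 1:6) {
      if (k == j) next
      tk <- Tm[, k]
      r <- r + (fin[, k] & (tk < tj | (tk == tj & k < j)))
    }
    fj <- fin[, j]
    key[fj] <- key[fj] + j * 7^(r[fj] - 1)
  }
  key
}

## decode a base-7 key back into the 6 sequence entries
.decodeKey <- function(key) {
  as.integer((key %/% 7^(0:5)) %% 7)
}

#' Exhaustive search for the representative threshold vector of a task
#'
#' Enumerates every combination of one ladder candidate per channel
#' (all-sentinel channels contribute a single fixed entry), encodes the
#' activation sequence of every acquisition under each combination, and
#' returns the combination whose modal sequence has the highest count.
#' Ties are broken toward the highest thresholds: combinations are
#' enumerated with each channel's ladder scanned from its highest candidate
#' down, and the first maximiser wins.
#'
#' @param recordings Acquisitions of one task (with a detected SoA).
#' @param annotations Matching \linkS4class{OnsetAnnotation} list.
#' @param ladders List of 6 \linkS4class{ThresholdLadder} objects (by
#'   channel).
#' @param windowMs Transient window length (ms) from the SoA.
#' @return List with \code{vector} (the representative
#'   \linkS4class{ThresholdVector}), \code{modalSequence} (integer length
#'   6), \code{modalCount}, \code{nCombinations}, and \code{nAcquisitions}.
#' @export
searchRepresentativeVector <- function(recordings, annotations, ladders,
                                       windowMs = 300) {
  if (!length(recordings)) stop("empty recording list")
  if (length(recordings) != length(annotations))
    stop("one annotation per recording is required")
  task <- unique(vapply(recordings, recLabel, character(1)))
  if (length(task) != 1L)
    stop("all recordings must share a task; got ",
         paste(task, collapse = ", "))
  nSteps <- unique(vapply(ladders, function(l) l@nSteps, integer(1)))
  if (length(nSteps) != 1L) stop("ladders must share the same depth")
  ladderValues <- lapply(ladders, function(l) l@values)
  keep <- !vapply(annotations, function(a) is.na(soaMs(a)), logical(1))
  if (!any(keep)) stop("no acquisition with a detected SoA")
  recordings <- recordings[keep]
  annotations <- annotations[keep]
  nAcq <- length(recordings)

  ## candidate index sets: all-sentinel channels collapse to one fixed entry
  nCand <- vapply(ladderValues, function(v)
    if (all(.isSentinel(v))) 1L else length(v), integer(1))
  combos <- as.matrix(do.call(
    expand.grid, rev(lapply(nCand, seq_len))))[, 6:1, drop = FALSE]
  colnames(combos) <- paste0("ch", 1:6)
  K <- nrow(combos)

  keys <- matrix(0, K, nAcq)
  for (a in seq_len(nAcq)) {
    ct <- .crossingTimeMatrix(recordings[[a]], soaMs(annotations[[a]]),
                              ladderValues, windowMs)
    Tm <- matrix(ct[cbind(rep(1:6, each = K), as.vector(combos))], K, 6)
    keys[, a] <- .sequenceKeys(Tm)
  }
  modalCounts <- apply(keys, 1L, function(r) max(tabulate(match(r, r))))
  best <- which.max(modalCounts)
  kr <- keys[best, ]
  counts <- tabulate(match(kr, unique(kr)))
  cand <- unique(kr)[counts == max(counts)]
  modalKey <- min(cand)

  values <- vapply(1:6, function(ch) ladderValues[[ch]][combos[best, ch]],
                   numeric(1))
  list(
    vector = new("ThresholdVector", task = task, values = values,
                 nSteps = as.integer(nSteps)),
    modalSequence = .decodeKey(modalKey),
    modalCount = as.integer(modalCounts[best]),
    nCombinations = K,
    nAcquisitions = nAcq
  )
}

#' Representative threshold matrix over the four tasks
#'
#' Runs \code{\link{initialMaxThreshold}}, \code{\link{buildLadder}} and
#' \code{\link{searchRepresentativeVector}} for each gesture task, yielding
#' the 4 x 6 representative threshold matrix.
#'
#' @param recordings Acquisitions of all tasks.
#' @param annotations Matching \linkS4class{OnsetAnnotation} list.
#' @param rest The dataset \linkS4class{RestModel}.
#' @param nSteps Ladder depth, 2..5.
#' @param windowMs Transient window length (ms).
#' @param tasks Task labels, default the four gestures.
#' @return List with \code{vectors} (named list of
#'   \linkS4class{ThresholdVector}), \code{matrix} (4 x 6 numeric),
#'   \code{details} (per-task search results).
#' @export
representativeThresholds <- function(recordings, annotations, rest,
                                     nSteps = 4, windowMs = 300,
                                     tasks = GESTURE_TASKS) {
  labels <- vapply(recordings, recLabel, character(1))
  details <- vectors <- stats::setNames(vector("list", length(tasks)), tasks)
  for (task in tasks) {
    idx <- which(labels == task)
    if (!length(idx)) stop("no acquisitions for task ", task)
    maxTh <- initialMaxThreshold(recordings[idx], annotations[idx], windowMs)
    ladders <- lapply(1:6, function(ch)
      buildLadder(maxTh[ch], thLow(rest), nSteps, channel = ch))
    res <- searchRepresentativeVector(recordings[idx], annotations[idx],
                                      ladders, windowMs)
    vectors[[task]] <- res$vector
    details[[task]] <- res
  }
  mat <- do.call(rbind, lapply(vectors, thresholdValues))
  dimnames(mat) <- list(tasks, paste0("emg", 1:6))
  list(vectors = vectors, matrix = mat, details = details)
}
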