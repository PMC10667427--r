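# Fixtures built in code: hand-crafted recordings with known crossing
# structure, independent brute-force oracles, and cached expensive objects
# shared across test files.

# recording from a bare matrix, padded metadata
makeRec <- function(x, fs = 1000, label = "Spherical", truth = list()) {
  envelopeRecording(x, fs = fs, label = label, truth = truth)
}

# all-zero 6-channel matrix of `ms` milliseconds at 1 kHz
zeroSamples <- function(ms = 4000) matrix(0, ms, 6)

# channel `ch` steps to `level` V at `atMs` and stays there
stepRec <- function(ch, atMs, level, ms = 4000, label = "Spherical") {
  x <- zeroSamples(ms)
  x[(atMs + 1):ms, ch] <- level
  makeRec(x, label = label)
}

# naive O(n * w) all-windows onset oracle: first start (ms) of a window of
# `sustainMs` samples all above `th`, NA when none
naiveFirstCrossing <- function(x, th, sustainMs) {
  n <- length(x)
  for (t in seq_len(n - sustainMs + 1)) {
    if (all(x[t:(t + sustainMs - 1)] > th)) return(t - 1)
  }
  NA_real_
}

# independent brute-force re-enumeration of the representative-vector
# search, using only the public encodeSequence; mirrors the documented
# enumeration order (channel 1 most significant, highest candidate first)
bruteForceSearch <- function(recordings, annotations, ladders, windowMs = 300) {
  vals <- lapply(ladders, function(l) l@values)
  nCand <- vapply(vals, function(v)
    if (all(v >= NA_VALUE - 1e-9)) 1L else length(v), integer(1))
  combos <- as.matrix(do.call(
    expand.grid, rev(lapply(nCand, seq_len))))[, 6:1, drop = FALSE]
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    v <- vapply(1:6, function(ch) vals[[ch]][combos[r, ch]], numeric(1))
    keys <- vapply(seq_along(recordings), function(i)
      paste(sequenceEntries(encodeSequence(
        recordings[[i]], soaMs(annotations[[i]]), v, windowMs)),
        collapse = ","), character(1))
    cnt <- max(table(keys))
    if (is.null(best) || cnt > best$count)
      best <- list(count = cnt, values = v, combo = combos[r, ])
  }
  best$nCombinations <- nrow(combos)
  best
}

# toy search instance: <= 3 ramping channels with randomised slopes so
# different candidate thresholds reorder the crossings
toySearchInstance <- function(activeChannels, nSteps, nAcq, seed) {
  set.seed(seed)
  recs <- lapply(seq_len(nAcq), function(a) {
    x <- zeroSamples(1000)
    for (ch in activeChannels) {
      start <- sample(500:560, 1)
      len <- sample(150:300, 1)
      ramp <- seq(0, 1, length.out = len)
      x[(start + 1):(start + len), ch] <- ramp
      x[(start + len + 1):1000, ch] <- 1
    }
    makeRec(x)
  })
  rest <- restModel(0.001, 0, 1)
  anns <- lapply(recs, detectSoa, rest = rest)
  maxTh <- initialMaxThreshold(recs, anns, windowMs = 300)
  ladders <- lapply(1:6, function(ch)
    buildLadder(maxTh[ch], thLow(rest), nSteps, channel = ch))
  list(recs = recs, anns = anns, ladders = ladders)
}

# ---- cached expensive objects (built on first use, shared across files) ----

.cache <- new.env(parent = emptyenv())

cachedRestRecs <- function() {
  if (is.null(.cache$restRecs))
    .cache$restRecs <- generateDataset(list(restProfile()),
                                       defaultNoiseModel(), 200,
                                       seed = 20260921)
  .cache$restRecs
}

cachedSubjectRecs <- function() {
  if (is.null(.cache$subjectRecs))
    .cache$subjectRecs <- generateDataset(defaultProfiles(),
                                          defaultNoiseModel(), 50,
                                          seed = 20260921)
  .cache$subjectRecs
}

cachedSubjectPipeline <- function() {
  if (is.null(.cache$subjectPipeline))
    .cache$subjectPipeline <- runSubjectPipeline(cachedSubjectRecs(),
                                                 nSteps = 4, seed = 20260921)
  .cache$subjectPipeline
}
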