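# Sequence encoding: ordinal ranking by crossing time, trailing zeros,
# the refined 12-element feature, and the timing summary.

# four channels crossing at staggered times, two never crossing
stairRec <- function() {
  x <- zeroSamples(2000)
  at <- c(ch4 = 620, ch1 = 650, ch3 = 700, ch5 = 750)
  lv <- c(1.2, 1.1, 1.0, 0.9)
  chs <- c(4, 1, 3, 5)
  for (i in seq_along(chs)) x[(at[i] + 1):2000, chs[i]] <- lv[i]
  makeRec(x)
}

test_that("channels are ranked by crossing time with trailing zeros", {
  rec <- stairRec()
  th <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  s <- encodeSequence(rec, soaMs = 500, th, windowMs = 300)
  expect_identical(sequenceEntries(s), c(4L, 1L, 3L, 5L, 0L, 0L))
  expect_equal(unname(crossingTimes(s)), c(620, 650, 700, 750))
  expect_identical(names(crossingTimes(s)), c("4", "1", "3", "5"))
})

test_that("sentinel thresholds and non-crossing channels are encoded 0", {
  rec <- stairRec()
  th <- c(0.5, 0.5, NA_VALUE, 0.5, 0.5, 0.5)   # ch3 forced Not Active
  s <- encodeSequence(rec, 500, th)
  expect_identical(sequenceEntries(s), c(4L, 1L, 5L, 0L, 0L, 0L))
  # nothing crosses a prohibitive vector
  none <- encodeSequence(rec, 500, rep(NA_VALUE, 6))
  expect_identical(sequenceEntries(none), rep(0L, 6))
  expect_length(crossingTimes(none), 0)
})

test_that("simultaneous crossings break toward the lower channel index", {
  x <- zeroSamples(1000)
  x[601:1000, c(2, 5)] <- 1
  s <- encodeSequence(makeRec(x), 500, rep(0.5, 6))
  expect_identical(sequenceEntries(s)[1:2], c(2L, 5L))
})

test_that("windows overrunning the recording are rejected", {
  rec <- stairRec()
  expect_error(encodeSequence(rec, 1900, rep(0.5, 6), windowMs = 300),
               "overruns")
})

test_that("lowering one channel's threshold never demotes it in the sequence", {
  recs <- cachedSubjectRecs()[seq(1, 200, by = 20)]
  rest <- estimateRestModel(cachedSubjectRecs(), x = 15)
  for (rec in recs) {
    ann <- detectSoa(rec, rest)
    if (is.na(soaMs(ann))) next
    th <- rep(0.6, 6)
    base <- sequenceEntries(encodeSequence(rec, soaMs(ann), th))
    for (ch in 1:6) {
      th2 <- th
      th2[ch] <- 0.3
      low <- sequenceEntries(encodeSequence(rec, soaMs(ann), th2))
      posBase <- match(ch, base)
      posLow <- match(ch, low)
      if (!is.na(posBase)) {
        expect_false(is.na(posLow))
        expect_lte(posLow, posBase)
      }
    }
  }
})

test_that("the refined feature concatenates four 3-element partial sequences", {
  res <- cachedSubjectPipeline()
  rest <- res$restModel
  rec <- cachedSubjectRecs()[["S1_Tip_001"]]
  ann <- detectSoa(rec, rest)
  f <- encodeFeatures(rec, soaMs(ann), res$thresholds$vectors)
  expect_length(f, 12)
  expect_true(all(f %in% 0:6))
  # each block is the prefix of the full sequence under that task vector
  for (i in seq_along(GESTURE_TASKS)) {
    full <- sequenceEntries(encodeSequence(
      rec, soaMs(ann), res$thresholds$vectors[[GESTURE_TASKS[i]]]))
    expect_identical(unname(f[(3 * i - 2):(3 * i)]), full[1:3])
  }
  expect_error(encodeFeatures(rec, soaMs(ann),
                              res$thresholds$vectors[1:3]), "each task")
})

test_that("an all-sentinel task vector contributes an all-zero block", {
  rec <- stairRec()
  vectors <- list(
    Spherical = new("ThresholdVector", task = "Spherical",
                    values = rep(0.5, 6), nSteps = 2L),
    Tip = new("ThresholdVector", task = "Tip", values = rep(NA_VALUE, 6),
              nSteps = 2L),
    Platform = new("ThresholdVector", task = "Platform",
                   values = rep(0.5, 6), nSteps = 2L),
    Point = new("ThresholdVector", task = "Point", values = rep(NA_VALUE, 6),
                nSteps = 2L))
  f <- encodeFeatures(rec, 500, vectors)
  expect_identical(unname(f[4:6]), rep(0L, 3))
  expect_identical(unname(f[10:12]), rep(0L, 3))
})

test_that("sequence invariants hold across a full synthetic dataset", {
  res <- cachedSubjectPipeline()
  f <- featureMatrix(res$table)
  for (b in 1:4) {
    blk <- f[, (3 * b - 2):(3 * b), drop = FALSE]
    nz <- apply(blk, 1, function(r) {
      v <- r[r > 0]
      !anyDuplicated(v) && all(r[seq_along(v)] > 0)  # distinct, trailing 0s
    })
    expect_true(all(nz))
  }
})

test_that("the timing summary reports per-rank latencies and entity", {
  s <- new("ActivationSequence", entries = c(2L, 5L, 1L, 0L, 0L, 0L),
           crossingTimesMs = c("2" = 600, "5" = 700, "1" = 750))
  out <- activationTimingSummary(list(s), soaMs = 500)
  expect_equal(unname(out$meanLatenciesMs), c(100, 200, 250))
  expect_equal(out$meanActivations, 3)
  expect_equal(out$meanActiveChannels, 3)
  expect_error(activationTimingSummary(list(), numeric()), "no sequences")
})

test_that("recovered latencies respect the generator's activation starts", {
  res <- cachedSubjectPipeline()
  recs <- cachedSubjectRecs()[recordingIds(res$table)]
  anns <- res$annotations[recordingIds(res$table)]
  lab <- vapply(recs, recLabel, character(1))
  idx <- which(lab == "Spherical")[1:20]
  seqs <- lapply(idx, function(i)
    encodeSequence(recs[[i]], soaMs(anns[[i]]),
                   res$thresholds$vectors[["Spherical"]]))
  soas <- vapply(idx, function(i) soaMs(anns[[i]]), numeric(1))
  out <- activationTimingSummary(seqs, soas)
  expect_true(all(diff(out$meanLatenciesMs) > 0))
  # every crossing happens after its channel's true activation start and
  # within the rise
  for (k in seq_along(idx)) {
    st <- truthInfo(recs[[idx[k]]])$startTimesMs
    ct <- crossingTimes(seqs[[k]])
    expect_true(all(ct >= st[names(ct)] - 1))
    expect_true(all(ct <= st[names(ct)] + 150))
  }
})
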