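# High-threshold ladders and the exhaustive representative-vector search.

test_that("the starting threshold is 80% of the in-window peak, averaged", {
  rest <- restModel(0.01, 0, 1)
  r1 <- stepRec(ch = 1, atMs = 500, level = 2.0)
  a1 <- detectSoa(r1, rest)
  th1 <- initialMaxThreshold(list(r1), list(a1))
  expect_equal(th1[1], 0.8 * 2.0)

  r2 <- stepRec(ch = 1, atMs = 500, level = 1.0)
  a2 <- detectSoa(r2, rest)
  th <- initialMaxThreshold(list(r1, r2), list(a1, a2))
  expect_equal(th[1], (0.8 * 2.0 + 0.8 * 1.0) / 2)
  # channels never active in any acquisition carry the sentinel
  expect_identical(unname(th[2:6]), rep(NA_VALUE, 5))
})

test_that("ladders decrement by 10% multiplicatively with sentinel filling", {
  lad <- buildLadder(0.8, thLow = 0.02, nSteps = 3)
  expect_equal(lad@values, c(0.8, 0.72, 0.648))
  lad5 <- buildLadder(0.8, thLow = 0.02, nSteps = 5)
  expect_equal(lad5@values, 0.8 * 0.9^(0:4))
  # candidates at or below the low threshold become the sentinel
  mixed <- buildLadder(0.8, thLow = 0.73, nSteps = 3)
  expect_equal(mixed@values, c(0.8, NA_VALUE, NA_VALUE))
  # a starting value below TH_Low yields an all-sentinel ladder
  expect_equal(buildLadder(0.01, thLow = 0.02, nSteps = 4)@values,
               rep(NA_VALUE, 4))
  expect_equal(buildLadder(NA_VALUE, thLow = 0.02, nSteps = 2)@values,
               rep(NA_VALUE, 2))
  expect_error(buildLadder(0.8, 0.02, nSteps = 1), "2..5")
  expect_error(buildLadder(0.8, 0.02, nSteps = 6), "2..5")
})

test_that("the search enumerates one candidate per non-sentinel channel", {
  inst <- toySearchInstance(activeChannels = c(1, 4), nSteps = 3,
                            nAcq = 2, seed = 1)
  res <- searchRepresentativeVector(inst$recs, inst$anns, inst$ladders)
  expect_equal(res$nCombinations, 3^2)
  inst2 <- toySearchInstance(activeChannels = c(2, 3, 5), nSteps = 2,
                             nAcq = 2, seed = 2)
  res2 <- searchRepresentativeVector(inst2$recs, inst2$anns, inst2$ladders)
  expect_equal(res2$nCombinations, 2^3)
})

test_that("the vectorised search agrees with brute-force re-enumeration", {
  cases <- list(list(ch = c(1, 4), steps = 2), list(ch = c(2, 5), steps = 3),
                list(ch = c(1, 3, 6), steps = 2),
                list(ch = c(2, 4, 5), steps = 3))
  for (i in seq_along(cases)) {
    inst <- toySearchInstance(cases[[i]]$ch, cases[[i]]$steps, nAcq = 4,
                              seed = 100 + i)
    res <- searchRepresentativeVector(inst$recs, inst$anns, inst$ladders)
    oracle <- bruteForceSearch(inst$recs, inst$anns, inst$ladders)
    expect_equal(res$modalCount, as.integer(oracle$count))
    expect_equal(thresholdValues(res$vector), oracle$values)
    expect_equal(res$nCombinations, oracle$nCombinations)
  }
})

test_that("ties are broken toward the highest thresholds", {
  # identical acquisitions: every combination reaches the maximal modal
  # count, so the first-enumerated (all-top-candidates) combination wins
  inst <- toySearchInstance(activeChannels = c(1, 2), nSteps = 3,
                            nAcq = 1, seed = 7)
  recs <- rep(inst$recs, 3)
  anns <- rep(inst$anns, 3)
  res <- searchRepresentativeVector(recs, anns, inst$ladders)
  expect_equal(res$modalCount, 3L)
  tops <- vapply(inst$ladders, function(l) l@values[1], numeric(1))
  expect_equal(thresholdValues(res$vector), tops)
})

test_that("the per-task representative matrix has one vector per task", {
  res <- cachedSubjectPipeline()
  expect_identical(rownames(res$thresholds$matrix), GESTURE_TASKS)
  expect_identical(dim(res$thresholds$matrix), c(4L, 6L))
  for (task in GESTURE_TASKS) {
    v <- res$thresholds$vectors[[task]]
    expect_identical(taskName(v), task)
    # channels outside the gesture's recruitment stay at the sentinel
    active <- defaultProfiles()[[task]]@activeChannels
    expect_true(all(thresholdValues(v)[-active] >= NA_VALUE - 1e-9))
    expect_true(all(thresholdValues(v)[active] < NA_VALUE))
  }
})

test_that("the searched modal sequences recover the generator orders", {
  res <- cachedSubjectPipeline()
  for (task in GESTURE_TASKS) {
    truthOrder <- defaultProfiles()[[task]]@order
    modal <- res$thresholds$details[[task]]$modalSequence
    expect_identical(modal[seq_along(truthOrder)], truthOrder)
  }
})
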