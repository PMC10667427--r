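# Offline accuracy accounting, the normality-gated method comparison, and
# the online MCR/MST simulation.

test_that("offline accuracy and confusion respect the test counts", {
  res <- cachedSubjectPipeline()
  ev <- res$evaluation
  expect_gte(ev$accuracy, 0)
  expect_lte(ev$accuracy, 100)
  truth <- gestureLabels(res$table[res$split$test])
  expect_equal(unname(rowSums(ev$confusion)),
               unname(table(factor(truth, sort(unique(truth))))),
               ignore_attr = TRUE)
  expect_equal(sum(ev$confusion), length(truth))
  # perfect and constant predictors bracket the accuracy scale
  set.seed(44)
  f <- pmax(do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(8 * 4, sd = 0.2), 8, 4), 2,
          5 * diag(4)[k, ], "+"))), 0)
  tabs <- featureTable(f, rep(GESTURE_TASKS, each = 8), kind = "ets")
  perfect <- trainClassifier(tabs, kind = "lda", seed = 1)
  expect_equal(offlineEvaluate(perfect, tabs)$accuracy, 100)
  coefs <- matrix(0, 1 + 4 + choose(4, 2), 4)  # intercept + expanded terms
  coefs[1, ] <- -10   # first class always wins on its intercept
  coefs[1, 1] <- 10
  constant <- new("GestureClassifier", kind = "nlr", featureKind = "ets",
                  classes = sort(GESTURE_TASKS), fit = list(coefs = coefs),
                  seed = 1, notes = character())
  expect_equal(offlineEvaluate(constant, tabs)$accuracy, 25)
})

test_that("summaries aggregate per-subject accuracies", {
  s <- summarizeAccuracies(c(90, 94, 92))
  expect_equal(unname(s["mean"]), 92)
  expect_equal(unname(s["sd"]), 2)
})

test_that("identical accuracy vectors are never declared different", {
  out <- compareMethods(rep(90, 6), rep(90, 6))
  expect_false(out$significant)
  expect_equal(out$p.value, 1)
  expect_identical(out$test, "Mann-Whitney U")
})

test_that("normality of the differences routes the test choice", {
  set.seed(12)
  a <- 90 + rnorm(20, sd = 1)
  bNormal <- a - 5 + rnorm(20, sd = 0.5)
  outN <- compareMethods(a, bNormal)
  expect_identical(outN$test, "paired t-test")
  expect_true(outN$significant)
  bCauchy <- a - 5 + rcauchy(20, scale = 3)
  outC <- compareMethods(a, bCauchy)
  expect_identical(outC$test, "Mann-Whitney U")
  expect_error(compareMethods(1:2, 2:3), "at least 3")
  expect_error(compareMethods(1:4, 1:3), "paired")
})

test_that("a large shift against small noise is significant", {
  set.seed(3)
  a <- 92 + rnorm(10, sd = 1)
  b <- a - 8 + rnorm(10, sd = 0.5)
  expect_true(compareMethods(a, b)$significant)
})

test_that("online simulation completes clean trials and accounts MCR/MST", {
  res <- cachedSubjectPipeline()
  trials <- cachedSubjectRecs()[recordingIds(res$table)[res$split$test]]
  out <- onlineSimulate(res$model, trials, res$restModel,
                        res$thresholds$vectors, seed = 5)
  pt <- out$perTask
  expect_setequal(pt$task, GESTURE_TASKS)
  expect_equal(pt$completed + (pt$attempts - pt$completed), pt$attempts)
  expect_equal(pt$mcr, 100 * pt$completed / pt$attempts)
  expect_true(all(pt$mcr >= 0 & pt$mcr <= 100))
  done <- Filter(function(o) o$completed, out$trials)
  expect_true(length(done) > 0)
  for (o in done) expect_gte(o$mstMs, 0)
  # MST is reported only over completed trials
  failed <- Filter(function(o) !o$completed, out$trials)
  for (o in failed) expect_true(is.na(o$mstMs))
})

test_that("with near-zero noise the online loop reaches full completion", {
  nm <- noiseModel(restMean = 0.012, restSd = 1e-4, correlationTime = 20)
  recs <- generateDataset(defaultProfiles(), nm, 10, seed = 31)
  res <- runSubjectPipeline(recs, nSteps = 3, seed = 31)
  trials <- recs[recordingIds(res$table)[res$split$test]]
  out <- onlineSimulate(res$model, trials, res$restModel,
                        res$thresholds$vectors, seed = 2)
  expect_true(all(out$perTask$mcr == 100))
  # decisions fall inside the transient window: MST is bounded by the
  # window end relative to movement onset plus detection latency
  for (o in out$trials) expect_lte(o$mstMs, 330)
  # MST equals the decision time minus the true movement onset
  ids <- names(trials)
  for (i in seq_along(out$trials)) {
    o <- out$trials[[i]]
    if (o$completed) expect_gte(o$decisionMs, 500)
  }
  expect_error(onlineSimulate(res$model, list(makeRec(zeroSamples(1000))),
                              res$restModel, res$thresholds$vectors),
               "ground-truth")
})
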