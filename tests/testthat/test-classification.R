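# The 80/20 split, the interaction expansion, and the four classifiers.

# small linearly separable 4-class problem with mild within-class spread
separableTable <- function(n = 15, seed = 42) {
  set.seed(seed)
  centers <- 5 * diag(4)
  f <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(n * 6, sd = 0.3), n, 6), 2,
          c(centers[k, ], 0, 0), "+")))
  featureTable(pmax(f, 0), rep(GESTURE_TASKS, each = n), kind = "ess")
}

test_that("the split is stratified, disjoint and deterministic", {
  labels <- rep(GESTURE_TASKS, each = 50)
  s <- splitRecordings(labels, trainFraction = 0.8, seed = 9)
  expect_length(s$train, 160)
  expect_length(s$test, 40)
  for (task in GESTURE_TASKS) {
    expect_equal(sum(labels[s$train] == task), 40)
    expect_equal(sum(labels[s$test] == task), 10)
  }
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), seq_along(labels))
  expect_identical(splitRecordings(labels, seed = 9), s)
  expect_false(identical(splitRecordings(labels, seed = 10), s))
  expect_error(splitRecordings(c("Tip", rep("Point", 5))), "fewer than 2")
})

test_that("interaction expansion appends all distinct pairwise products", {
  x <- c(a = 2, b = 3)
  expect_equal(unname(expandInteractions(x)), c(2, 3, 6))
  expect_equal(unname(expandInteractions(rep(0, 5))), rep(0, 5 + 10))
  x12 <- rnorm(12)
  ex <- expandInteractions(x12)
  expect_length(ex, 78)   # 12 + choose(12, 2)
  # oracle: explicit double loop over distinct pairs
  oracle <- x12
  for (i in 1:11) for (j in (i + 1):12) oracle <- c(oracle, x12[i] * x12[j])
  expect_equal(unname(ex), oracle)
  # matrix input expands row-wise
  M <- matrix(rnorm(24), 2, 12)
  exM <- expandInteractions(M)
  expect_equal(dim(exM), c(2L, 78L))
  expect_equal(unname(exM[1, ]), unname(expandInteractions(M[1, ])))
  expect_error(expandInteractions(x12, degree = 3), "degree-2")
})

test_that("all four classifiers separate a linearly separable problem", {
  tab <- separableTable()
  s <- splitFeatureTable(tab, seed = 3)
  for (kind in c("nlr", "svm", "ann", "lda")) {
    hyper <- if (kind == "ann") list(layers = 1L, neurons = 6L, maxit = 150L)
             else list()
    model <- trainClassifier(s$train, kind = kind, hyper = hyper, seed = 11)
    acc <- offlineEvaluate(model, s$test)$accuracy
    expect_equal(acc, 100, info = kind)
  }
})

test_that("LDA fits exactly one binary discriminant per class", {
  tab <- separableTable()
  model <- trainClassifier(tab, kind = "lda", seed = 1)
  expect_length(model@fit$models, 4)
  expect_identical(names(model@fit$models), GESTURE_TASKS[order(GESTURE_TASKS)])
})

test_that("degenerate within-class variance triggers the LDA fallback", {
  f <- cbind(rep(c(0, 1, 2, 3), each = 5),
             matrix(2, 20, 5))   # columns 2..6 constant
  tab <- featureTable(f, rep(GESTURE_TASKS, each = 5), kind = "ess")
  model <- trainClassifier(tab, kind = "lda", seed = 1)
  expect_identical(unname(model@fit$models[[1]]$keep), 1L)
  # an entirely constant feature set degenerates to the prior, with a note
  f0 <- matrix(1, 20, 6)
  tab0 <- featureTable(f0, rep(GESTURE_TASKS, each = 5), kind = "ess")
  m0 <- trainClassifier(tab0, kind = "lda", seed = 1)
  expect_true(length(m0@notes) > 0)
  expect_length(classify(m0, tab0), 20)
})

test_that("training and prediction are deterministic given the seed", {
  tab <- separableTable(seed = 7)
  for (kind in c("nlr", "svm", "ann", "lda")) {
    hyper <- if (kind == "ann") list(layers = 2L, neurons = 5L, maxit = 100L)
             else list()
    m1 <- trainClassifier(tab, kind = kind, hyper = hyper, seed = 5)
    m2 <- trainClassifier(tab, kind = kind, hyper = hyper, seed = 5)
    expect_identical(classify(m1, tab), classify(m2, tab), info = kind)
  }
})

test_that("the harness accepts any feature kind unchanged", {
  res <- cachedSubjectPipeline()
  recs <- cachedSubjectRecs()[recordingIds(res$table)]
  anns <- res$annotations[recordingIds(res$table)]
  idx <- seq(1, length(recs), by = 5)   # spans all four tasks
  for (kind in c("ets", "ess")) {
    tab <- baselineFeatureTable(recs[idx], anns[idx], kind = kind)
    model <- trainClassifier(tab, kind = "lda", seed = 2)
    expect_identical(model@featureKind, kind)
    expect_length(classify(model, tab), length(idx))
  }
  # feature-kind mismatch between model and table is an error
  model <- res$model
  ess <- baselineFeatureTable(recs[1:4], anns[1:4], kind = "ess")
  expect_error(classify(model, ess), "mismatch")
})

test_that("shuffled labels drop held-out accuracy to chance", {
  res <- cachedSubjectPipeline()
  tab <- res$table
  set.seed(101)
  shuffled <- featureTable(featureMatrix(tab),
                           sample(gestureLabels(tab)),
                           recordingIds(tab), kind = "sequence12")
  s <- splitFeatureTable(shuffled, seed = 101)
  model <- trainClassifier(s$train, kind = "nlr", seed = 101)
  acc <- offlineEvaluate(model, s$test)$accuracy
  expect_gte(acc, 5)
  expect_lte(acc, 45)   # chance is 25% on four balanced classes
})
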