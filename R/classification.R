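## The four reference classifiers on any feature table, with the stratified
## 80/20 per-task split and the interaction expansion used by the non-linear
## logistic regression.

#' Stratified train/test split of recording indices
#'
#' Per task, \code{round(trainFraction * n)} recordings go to the training
#' set; the split is deterministic given the seed and train and test are
#' disjoint.
#'
#' @param labels Gesture label of each recording.
#' @param trainFraction Fraction assigned to training (0.8).
#' @param seed Integer seed.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
splitRecordings <- function(labels, trainFraction = 0.8, seed = 1) {
  labels <- unname(labels)
  set.seed(as.integer(seed %% 2147483647))
  train <- integer()
  for (task in sort(unique(labels))) {
    idx <- which(labels == task)
    if (length(idx) < 2L)
      stop("task ", task, " has fewer than 2 recordings")
    nTrain <- round(trainFraction * length(idx))
    train <- c(train, sort(sample(idx, nTrain)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' @rdname splitRecordings
#' @param table A \linkS4class{FeatureTable}.
#' @return For \code{splitFeatureTable}, a list with the \code{train} and
#'   \code{test} \linkS4class{FeatureTable}s.
#' @export
splitFeatureTable <- function(table, trainFraction = 0.8, seed = 1) {
  s <- splitRecordings(gestureLabels(table), trainFraction, seed)
  list(train = table[s$train], test = table[s$test])
}

#' Degree-2 interaction expansion
#'
#' Appends to the original features all pairwise products of distinct
#' features, the extra polynomial terms consumed by the non-linear logistic
#' regression. A 12-feature input yields 12 + 66 = 78 features.
#'
#' @param x Numeric vector or matrix (rows = observations).
#' @param degree Only degree 2 is supported.
#' @return Expanded vector or matrix.
#' @export
expandInteractions <- function(x, degree = 2) {
  if (degree != 2) stop("only degree-2 interaction expansion is supported")
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1L) else as.matrix(x)
  p <- ncol(X)
  pairs <- utils::combn(p, 2L)
  prod <- X[, pairs[1L, ], drop = FALSE] * X[, pairs[2L, ], drop = FALSE]
  colnames(prod) <- paste0("f", pairs[1L, ], "x", pairs[2L, ])
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  out <- cbind(X, prod)
  if (vec) out[1L, ] else out
}

## columns with (pooled within-group) variance exactly zero break MASS::lda;
## they carry no discriminant information and are dropped
.ldaKeepColumns <- function(X, grouping) {
  within <- rep(0, ncol(X))
  for (g in unique(grouping)) {
    Xg <- X[grouping == g, , drop = FALSE]
    if (nrow(Xg) > 1L)
      within <- within + colSums(sweep(Xg, 2L, colMeans(Xg))^2)
  }
  which(within / nrow(X) > 1e-12)
}

#' Train a gesture classifier
#'
#' Four kinds are supported:
#' \describe{
#'   \item{nlr}{Non-linear logistic regression: one-vs-all logistic models
#'     on degree-2 interaction-expanded features; prediction is the argmax
#'     of the class probabilities (0.5 decision threshold in the binary
#'     case).}
#'   \item{svm}{Support vector machine, RBF kernel by default
#'     (\code{hyper$kernel = "linear"} for the linear variant).}
#'   \item{ann}{Multilayer perceptron with logistic activations and one
#'     output unit per class; 1..5 hidden layers of equal width. When
#'     \code{hyper$layers} is NULL the depth is selected by 5-fold
#'     validation on the training split.}
#'   \item{lda}{One-vs-all linear discriminant analysis; columns with zero
#'     within-group variance are dropped per discriminant, and a degenerate
#'     discriminant falls back to the class prior (noted on the model).}
#' }
#'
#' @param table Training \linkS4class{FeatureTable}.
#' @param kind Classifier kind.
#' @param hyper Named list of kind-specific hyperparameters.
#' @param seed Seed for any stochastic part of training.
#' @return A \linkS4class{GestureClassifier}.
#' @export
trainClassifier <- function(table, kind = c("nlr", "svm", "ann", "lda"),
                            hyper = list(), seed = 1) {
  kind <- match.arg(kind)
  X <- featureMatrix(table)
  y <- gestureLabels(table)
  if (nrow(X) == 0L) stop("empty training table")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("at least 2 classes are required")
  notes <- character()
  fit <- switch(kind,
    nlr = {
      Xe <- cbind(1, expandInteractions(X))
      coefs <- vapply(classes, function(cl) {
        b <- suppressWarnings(
          stats::glm.fit(Xe, as.numeric(y == cl),
                         family = stats::binomial())$coefficients)
        b[is.na(b)] <- 0
        b
      }, numeric(ncol(Xe)))
      list(coefs = coefs, threshold = hyper$threshold %||% 0.5)
    },
    svm = {
      set.seed(as.integer(seed %% 2147483647))
      model <- e1071::svm(x = X, y = factor(y, levels = classes),
                          kernel = hyper$kernel %||% "radial",
                          cost = hyper$cost %||% 1,
                          gamma = hyper$gamma %||% (1 / ncol(X)),
                          scale = FALSE)
      list(model = model)
    },
    ann = {
      neurons <- hyper$neurons %||% 10L
      maxit <- hyper$maxit %||% 300L
      center <- colMeans(X)
      scl <- apply(X, 2L, stats::sd)
      scl[scl < 1e-12] <- 1
      Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")
      Y <- vapply(classes, function(cl) as.numeric(y == cl),
                  numeric(nrow(Xs)))
      layers <- hyper$layers
      if (is.null(layers)) {
        layers <- .selectMlpDepth(Xs, Y, y, neurons, seed, maxit)
        notes <- c(notes, sprintf("depth %d selected by 5-fold validation",
                                  layers))
      }
      mlp <- .mlpTrain(Xs, Y, layers, neurons, seed, maxit)
      list(mlp = mlp, center = center, scale = scl)
    },
    lda = {
      models <- lapply(classes, function(cl) {
        g <- factor(y == cl, levels = c(FALSE, TRUE))
        keep <- .ldaKeepColumns(X, g)
        if (!length(keep)) {
          notes <<- c(notes, sprintf(
            "degenerate covariance for class %s: prior fallback", cl))
          return(list(prior = mean(y == cl)))
        }
        m <- suppressWarnings(
          MASS::lda(x = X[, keep, drop = FALSE], grouping = g, tol = 1e-10))
        list(model = m, keep = keep)
      })
      names(models) <- classes
      list(models = models)
    })
  new("GestureClassifier", kind = kind, featureKind = featureKind(table),
      classes = classes, fit = fit, seed = as.numeric(seed), notes = notes)
}

## 5-fold validation over hidden depths 1..5 on the training split
.selectMlpDepth <- function(Xs, Y, y, neurons, seed, maxit,
                            depths = 1:5, folds = 5L) {
  set.seed(as.integer(seed %% 2147483647))
  fold <- sample(rep_len(seq_len(folds), nrow(Xs)))
  acc <- vapply(depths, function(d) {
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < ncol(Y)) next
      m <- .mlpTrain(Xs[tr, , drop = FALSE], Y[tr, , drop = FALSE], d,
                     neurons, seed + f, maxit)
      P <- .mlpPredictProb(m, Xs[!tr, , drop = FALSE])
      hits <- hits + sum(max.col(P, ties.method = "first") ==
                           max.col(Y[!tr, , drop = FALSE],
                                   ties.method = "first"))
    }
    hits
  }, numeric(1))
  depths[which.max(acc)]
}

#' @rdname classify
#' @export
setMethod("classify", "GestureClassifier", function(model, newdata) {
  X <- if (is(newdata, "FeatureTable")) {
    if (!identical(featureKind(newdata), model@featureKind))
      stop("feature kind mismatch: model expects ", model@featureKind,
           ", table holds ", featureKind(newdata))
    featureMatrix(newdata)
  } else as.matrix(newdata)
  classes <- model@classes
  switch(model@kind,
    nlr = {
      P <- stats::plogis(cbind(1, expandInteractions(X)) %*%
                           model@fit$coefs)
      classes[max.col(P, ties.method = "first")]
    },
    svm = as.character(stats::predict(model@fit$model, X)),
    ann = {
      Xs <- sweep(sweep(X, 2L, model@fit$center), 2L, model@fit$scale, "/")
      P <- .mlpPredictProb(model@fit$mlp, Xs)
      classes[max.col(P, ties.method = "first")]
    },
    lda = {
      P <- vapply(classes, function(cl) {
        m <- model@fit$models[[cl]]
        if (is.null(m$model)) return(rep(m$prior, nrow(X)))
        stats::predict(m$model,
                       X[, m$keep, drop = FALSE])$posterior[, "TRUE"]
      }, numeric(nrow(X)))
      if (nrow(X) == 1L) P <- matrix(P, 1L)
      classes[max.col(P, ties.method = "first")]
    })
})
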