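## Offline accuracy reporting, the normality-gated inter-method comparison,
## and the online simulation with motion completion rate (MCR) and motion
## selection time (MST).

#' Offline accuracy of a trained model on a test table
#'
#' @param model A \linkS4class{GestureClassifier}.
#' @param testTable A \linkS4class{FeatureTable} of the model's feature
#'   kind.
#' @return List with \code{accuracy} (percent), \code{perClass} (percent
#'   per true class), and \code{confusion} (truth x prediction counts).
#' @export
offlineEvaluate <- function(model, testTable) {
  truth <- gestureLabels(testTable)
  pred <- classify(model, testTable)
  lev <- sort(unique(c(truth, pred)))
  confusion <- table(truth = factor(truth, lev), pred = factor(pred, lev))
  perClass <- 100 * diag(prop.table(confusion, 1L))[sort(unique(truth))]
  list(accuracy = 100 * mean(pred == truth), perClass = perClass,
       confusion = confusion)
}

#' Mean and standard deviation of per-dataset accuracies
#'
#' @param accuracies Numeric vector of accuracies (percent), one per
#'   dataset/subject.
#' @return Named numeric with \code{mean} and \code{sd}.
#' @export
summarizeAccuracies <- function(accuracies) {
  c(mean = mean(accuracies), sd = stats::sd(accuracies))
}

#' Normality-gated comparison of two accuracy vectors
#'
#' The paired differences are tested for normality (Shapiro-Wilk at the
#' same alpha); normal differences route to a paired t-test, otherwise a
#' Mann-Whitney U test is applied (unpaired, as named). Two-sided.
#'
#' @param a,b Equal-length accuracy vectors (one entry per dataset).
#' @param alpha Significance level.
#' @return List with \code{test}, \code{statistic}, \code{p.value},
#'   \code{significant} and \code{normalityP}.
#' @export
compareMethods <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("'a' and 'b' must be paired")
  if (length(a) < 3L) stop("at least 3 paired values are required")
  d <- a - b
  normalityP <- tryCatch(stats::shapiro.test(d)$p.value,
                         error = function(e) 0)
  if (normalityP >= alpha) {
    ht <- stats::t.test(a, b, paired = TRUE)
    test <- "paired t-test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    test <- "Mann-Whitney U"
  }
  p <- ht$p.value
  if (is.na(p)) p <- 1   # fully tied samples carry no evidence
  list(test = test, statistic = unname(ht$statistic),
       p.value = p, significant = p < alpha,
       normalityP = normalityP)
}

#' Online simulation of sequence-based gesture selection
#'
#' Each trial is processed causally: at every new activation event, once at
#' least \code{minActivations} activations are available under at least one
#' task threshold vector (and always at the end of the transient window),
#' the partial 12-element feature available at that instant is encoded and
#' classified. A trial is completed when the true class is output before
#' the trial ends; the motion selection time is the first correct
#' classification time minus the movement onset.
#'
#' @param model A trained \linkS4class{GestureClassifier} (sequence12).
#' @param trials List of \linkS4class{EnvelopeRecording} objects carrying
#'   ground truth (movement onset).
#' @param rest The dataset \linkS4class{RestModel}.
#' @param vectors Named list of the four task threshold vectors.
#' @param windowMs Transient window length (ms).
#' @param sustainMs Sustain window of the onset detector (ms).
#' @param minActivations Activations required before a decision fires.
#' @param keep Elements kept per task partial sequence.
#' @param seed Optional seed to shuffle the presentation order.
#' @return List with \code{perTask} (data.frame: attempts, completed, MCR
#'   percent, mean and sd MST ms) and \code{trials} (per-trial outcomes).
#' @export
onlineSimulate <- function(model, trials, rest, vectors, windowMs = 300,
                           sustainMs = 50, minActivations = 3L, keep = 3L,
                           seed = NULL) {
  if (!is.null(seed)) {
    set.seed(as.integer(seed %% 2147483647))
    trials <- trials[sample(seq_along(trials))]
  }
  outcomes <- lapply(trials, function(rec) {
    truth <- truthInfo(rec)
    if (!length(truth) || is.na(truth$onsetMs %||% NA_real_))
      stop("online trials require a ground-truth movement onset")
    res <- list(task = recLabel(rec), completed = FALSE, mstMs = NA_real_,
                decisionMs = NA_real_)
    ann <- detectSoa(rec, rest, sustainMs = sustainMs)
    if (is.na(soaMs(ann))) return(res)
    soa <- soaMs(ann)
    ## crossing times per task vector, computed once; the causal loop
    ## replays them in event order
    cross <- lapply(vectors, function(v)
      crossingTimes(encodeSequence(rec, soa, v, windowMs)))
    events <- sort(unique(unlist(cross, use.names = FALSE)))
    decisionTimes <- events[vapply(events, function(t)
      any(vapply(cross, function(ct) sum(ct <= t), numeric(1)) >=
            minActivations), logical(1))]
    decisionTimes <- unique(c(decisionTimes, soa + windowMs))
    for (t in decisionTimes) {
      feat <- unlist(lapply(GESTURE_TASKS, function(task) {
        ct <- cross[[task]]
        ct <- ct[ct <= t]
        ch <- as.integer(names(ct))
        c(ch, integer(keep))[seq_len(keep)]
      }))
      pred <- classify(model, matrix(feat, 1L))
      if (pred == recLabel(rec)) {
        res$completed <- TRUE
        res$decisionMs <- t
        res$mstMs <- t - truth$onsetMs
        break
      }
    }
    res
  })
  task <- vapply(outcomes, `[[`, character(1), "task")
  completed <- vapply(outcomes, `[[`, logical(1), "completed")
  mst <- vapply(outcomes, `[[`, numeric(1), "mstMs")
  perTask <- do.call(rbind, lapply(sort(unique(task)), function(tk) {
    sel <- task == tk
    ok <- completed & sel
    data.frame(task = tk, attempts = sum(sel), completed = sum(ok),
               mcr = 100 * mean(completed[sel]),
               mstMeanMs = if (any(ok)) mean(mst[ok]) else NA_real_,
               mstSdMs = if (sum(ok) > 1L) stats::sd(mst[ok]) else NA_real_)
  }))
  list(perTask = perTask, trials = outcomes)
}
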