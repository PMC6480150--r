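# Evaluation: confusion metrics, repeated stratified 2:1 splitting, the
# Welch t-test feature screen used for baselines, and the cumulative
# feature-group ablation harness.

#' Accuracy, precision and recall from confusion counts
#'
#' The hypertensive class is the positive class: ACC = (TP+TN)/total,
#' PRE = TP/(TP+FP), REC = TP/(TP+FN).
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return Named list with `acc`, `pre`, `rec`; a metric whose denominator
#'   is zero is `NaN`.
#' @examples
#' classifierMetrics(tp = 3, tn = 4, fp = 1, fn = 2)
#' @export
classifierMetrics <- function(tp, tn, fp, fn) {
  tot <- tp + tn + fp + fn
  if (tot == 0) stop("classifierMetrics: no evaluated subjects")
  list(acc = (tp + tn) / tot,
       pre = if (tp + fp > 0) tp / (tp + fp) else NaN,
       rec = if (tp + fn > 0) tp / (tp + fn) else NaN)
}

#' Stratified 2:1 train/test split
#'
#' Each class contributes approximately 2/3 of its subjects to the
#' training set. Per-class training counts follow largest-remainder
#' rounding of the class quotas against the floored total (so 61
#' hypertensive + 67 normotensive subjects split into 85 training and 43
#' test subjects as 41/44 vs 20/23); remainder ties are resolved in
#' favour of the hypertensive class. Deterministic under `seed`.
#'
#' @param labels character vector of class labels.
#' @param ratio training fraction.
#' @param seed integer RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(labels, ratio = 2 / 3, seed = 1L) {
  classes <- .CLASS_LEVELS[.CLASS_LEVELS %in% labels]
  if (!length(classes)) classes <- unique(labels)
  if (length(classes) < 2L)
    stop("stratifiedSplit: need at least 2 classes, found ",
         length(classes))
  cnt <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(cnt < 3L)) stop("stratifiedSplit: need at least 3 subjects per class")
  quota <- cnt * ratio
  totTrain <- floor(sum(quota) + 1e-9)
  nTrain <- floor(quota)
  leftover <- totTrain - sum(nTrain)
  if (leftover > 0) {
    # distribute by largest remainder; ties favour earlier (hypertensive) class
    o <- order(-(quota - nTrain), seq_along(quota))
    nTrain[o[seq_len(leftover)]] <- nTrain[o[seq_len(leftover)]] + 1L
  }
  .with_seed(seed, {
    train <- integer(0)
    for (i in seq_along(classes)) {
      idx <- which(labels == classes[i])
      train <- c(train, sample(idx, nTrain[i]))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Train the mining + coverage pipeline on a labeled feature table
#'
#' Fits the equal-width discretizer on the training rows, mines class
#' association rules and builds the coverage classifier.
#'
#' @param training labeled feature data.frame (`label` + feature columns).
#' @param minSup,minConf mining thresholds.
#' @param maxLen rule length cap passed to [mineCARs()].
#' @param features feature subset to use (default all present).
#' @return A [CARClassifier-class].
#' @export
trainCARClassifier <- function(training, minSup = 0.3, minConf = 0.8,
                               maxLen = Inf, features = NULL) {
  scheme <- fitDiscretizer(training, features)
  D <- transactionize(training, scheme)
  rules <- mineCARs(D, minSup, minConf, maxLen)
  buildClassifier(rules, D, scheme, minSup, minConf)
}

#' Repeated stratified evaluation of the full pipeline
#'
#' Repeats the stratified 2:1 split `nRepeats` times (fresh random
#' partition each time), trains the miner + coverage classifier on each
#' training set, evaluates on the held-out set, and averages accuracy,
#' precision and recall over the repeats.
#'
#' @param featureTable labeled feature data.frame.
#' @param minSup,minConf,maxLen mining parameters.
#' @param features feature subset to use.
#' @param nRepeats number of random partitions.
#' @param seed base seed; repeat r uses `seed + r - 1`.
#' @return List with `mean` (named acc/pre/rec) and `perSplit`
#'   (data.frame of per-repeat metrics and seeds).
#' @export
repeatedEvaluation <- function(featureTable, minSup = 0.3, minConf = 0.8,
                               maxLen = Inf, features = NULL,
                               nRepeats = 10L, seed = 1L) {
  res <- data.frame(seed = seed + seq_len(nRepeats) - 1L,
                    acc = NA_real_, pre = NA_real_, rec = NA_real_)
  for (r in seq_len(nRepeats)) {
    sp <- stratifiedSplit(featureTable$label, seed = res$seed[r])
    model <- trainCARClassifier(featureTable[sp$train, , drop = FALSE],
                                minSup, minConf, maxLen, features)
    pred <- predict(model, featureTable[sp$test, , drop = FALSE])
    truth <- unname(classCodes()[featureTable$label[sp$test]])
    m <- classifierMetrics(tp = sum(pred == 1L & truth == 1L),
                           tn = sum(pred == 2L & truth == 2L),
                           fp = sum(pred == 1L & truth == 2L),
                           fn = sum(pred == 2L & truth == 1L))
    res$acc[r] <- m$acc; res$pre[r] <- m$pre; res$rec[r] <- m$rec
  }
  list(mean = c(acc = mean(res$acc), pre = mean(res$pre),
                rec = mean(res$rec)),
       perSplit = res)
}

#' Welch t-test feature screen
#'
#' Two-sample (Welch) t-test per feature between the classes; features
#' with p below `alpha` are retained. Used to select features for
#' baseline classifiers only -- the rule miner consumes all features.
#'
#' @param featureTable labeled feature data.frame.
#' @param alpha significance threshold.
#' @param features features to screen (default all present).
#' @return List with `retained` (character), `pvalues` (named numeric).
#'   Features constant within both groups are skipped with a warning.
#' @export
ttestScreen <- function(featureTable, alpha = 0.05, features = NULL) {
  if (is.null(features))
    features <- intersect(featureNames(), names(featureTable))
  g <- featureTable$label
  if (length(unique(g)) != 2L) stop("ttestScreen: need both classes")
  p <- stats::setNames(rep(NA_real_, length(features)), features)
  for (f in features) {
    x <- featureTable[[f]][g == "hypertensive"]
    y <- featureTable[[f]][g == "normotensive"]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      warning("ttestScreen: feature '", f, "' constant in both groups, skipped")
      next
    }
    p[f] <- stats::t.test(x, y)$p.value
  }
  list(retained = names(p)[!is.na(p) & p < alpha], pvalues = p)
}

#' Cumulative feature-group ablation
#'
#' Runs [repeatedEvaluation()] on the cumulative feature groups TD,
#' TD+FD, TD+FD+ND and TD+FD+ND+BF (time domain, frequency domain,
#' non-linear domain, BCG fluctuation).
#'
#' @param featureTable labeled feature data.frame.
#' @param groups ordered group names to accumulate.
#' @param ... passed to [repeatedEvaluation()].
#' @return data.frame with one row per cumulative combination and the
#'   mean acc/pre/rec.
#' @export
ablation <- function(featureTable, groups = c("TD", "FD", "ND", "BF"), ...) {
  gmap <- featureGroups()
  unknown <- setdiff(groups, names(gmap))
  if (length(unknown))
    stop("ablation: unknown feature group(s): ", paste(unknown, collapse = ", "))
  out <- data.frame(combination = character(0), acc = numeric(0),
                    pre = numeric(0), rec = numeric(0))
  feats <- character(0)
  for (i in seq_along(groups)) {
    feats <- c(feats, gmap[[groups[i]]])
    ev <- repeatedEvaluation(featureTable, features = feats, ...)
    out <- rbind(out, data.frame(
      combination = paste(groups[seq_len(i)], collapse = "+"),
      acc = ev$mean[["acc"]], pre = ev$mean[["pre"]], rec = ev$mean[["rec"]]))
  }
  out
}
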