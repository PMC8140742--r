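# Cross-validation harness: repeated stratified k-fold CV of a pluggable
# probabilistic classifier on an encoded dataset, the paired two-group CV,
# and the five performance metrics.

#' Random-forest classifier (default model)
#'
#' The default pluggable classifier: a random forest with library default
#' parameters. A classifier is a list with elements \code{fit(x, y)}
#' returning a fitted model and \code{predictProb(model, x)} returning the
#' positive-class probability per row.
#'
#' @param ntree Number of trees (library default 500).
#' @return A classifier list usable with [repeatedStratifiedCV()].
#' @export
rfClassifier <- function(ntree = 500) {
  list(
    name = "random_forest",
    fit = function(x, y) {
      randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                 ntree = ntree)
    },
    predictProb = function(model, x) {
      unname(stats::predict(model, newdata = x, type = "prob")[, "1"])
    })
}

#' Nearest-centroid probabilistic classifier
#'
#' A deterministic, RNG-free stub classifier: class probability from the
#' softmax of negative euclidean distances to the two class centroids.
#' Useful for tests and quick runs.
#'
#' @return A classifier list usable with [repeatedStratifiedCV()].
#' @export
centroidClassifier <- function() {
  list(
    name = "nearest_centroid",
    fit = function(x, y) {
      list(c0 = colMeans(x[y == 0, , drop = FALSE]),
           c1 = colMeans(x[y == 1, , drop = FALSE]))
    },
    predictProb = function(model, x) {
      d0 <- sqrt(rowSums(sweep(x, 2L, model$c0)^2))
      d1 <- sqrt(rowSums(sweep(x, 2L, model$c1)^2))
      unname(1 / (1 + exp(d1 - d0)))
    })
}

# stratified fold assignment: per class, shuffle and deal round-robin; the
# shuffling seed of repetition r is seed + r
.make_partitions <- function(ids, labels, k, repeats, seed) {
  lapply(seq_len(repeats), function(r) {
    .with_seed(seed + r, {
      fold_of <- integer(length(ids))
      for (cl in c(1L, 0L)) {
        pos <- which(labels == cl)
        pos <- pos[sample.int(length(pos))]
        fold_of[pos] <- rep_len(seq_len(k), length(pos))
      }
      lapply(seq_len(k), function(f) ids[fold_of == f])
    })
  })
}

# run one CV given precomputed partitions (shared by the paired variant)
.run_cv <- function(mat, labels, partitions, classifier, seed, spec) {
  ids <- rownames(mat)
  folds <- list()
  for (r in seq_along(partitions)) {
    for (f in seq_along(partitions[[r]])) {
      test_ids <- partitions[[r]][[f]]
      train_ids <- setdiff(ids, test_ids)
      ytr <- labels[train_ids]
      if (length(unique(ytr)) < 2L)
        stop("invalid input: a training split lost one class entirely")
      model <- .with_seed(seed + 1000L * r + f,
        classifier$fit(mat[train_ids, , drop = FALSE], unname(ytr)))
      prob <- classifier$predictProb(model, mat[test_ids, , drop = FALSE])
      prob <- pmin(pmax(prob, 0), 1)
      folds[[length(folds) + 1L]] <- list(
        repetition = r, fold = f, ids = test_ids,
        truth = unname(labels[test_ids]), prob = prob,
        pred = as.integer(prob >= 0.5))
    }
  }
  new("CVResult", spec = spec, folds = folds)
}

#' Repeated stratified k-fold cross-validation
#'
#' Splits the encoded dataset into \code{k} stratified folds and repeats
#' the CV \code{repeats} times (defaults 5 and 10, i.e. 50 fold rows). Per
#' fold, the classifier is fitted on the training rows under a fixed
#' derived seed and evaluated on the held-out rows; predicted class is 1
#' iff the positive-class probability is at least 0.5.
#'
#' @param e An [EncodedSet-class].
#' @param labels Named 0/1 vector covering the encoded record ids (e.g.
#'   [classLabels()] of the source dataset).
#' @param k Number of folds (>= 2).
#' @param repeats Number of repetitions (>= 1).
#' @param seed Integer seed; repetition r shuffles folds with
#'   \code{seed + r}.
#' @param classifier Classifier list; default [rfClassifier()].
#' @return A [CVResult-class] with \code{k * repeats} fold rows.
#' @export
repeatedStratifiedCV <- function(e, labels, k = 5L, repeats = 10L,
                                 seed = 1L, classifier = rfClassifier()) {
  mat <- featureMatrix(e)
  ids <- rownames(mat)
  labels <- labels[ids]
  if (anyNA(labels)) stop("invalid input: labels missing for some records")
  if (k < 2L) stop("invalid parameter: k must be >= 2")
  if (repeats < 1L) stop("invalid parameter: repeats must be >= 1")
  if (nrow(mat) < k)
    stop(sprintf("invalid parameter: n = %d < k = %d folds", nrow(mat), k))
  if (length(unique(labels)) < 2L)
    stop("invalid input: both classes must be present")
  if (min(table(labels)) < 2L)
    stop("invalid input: each class needs >= 2 records")
  parts <- .make_partitions(ids, labels, k, repeats, seed)
  .run_cv(mat, labels, parts, classifier, seed, e@spec)
}

#' Paired cross-validation of two encoded datasets
#'
#' Reduces both datasets to the intersection of their record ids and runs
#' the same seed-driven fold partition on both, so row i of both results
#' covers identical held-out records. This traceability is the
#' prerequisite for the classifier-similarity measures.
#'
#' @param e1,e2 [EncodedSet-class] objects over overlapping records.
#' @inheritParams repeatedStratifiedCV
#' @return List of two [CVResult-class] objects, in input order.
#' @export
pairedTwoGroupCV <- function(e1, e2, labels, k = 5L, repeats = 10L,
                             seed = 1L, classifier = rfClassifier()) {
  shared <- intersect(rownames(featureMatrix(e1)),
                      rownames(featureMatrix(e2)))
  if (length(shared) == 0L)
    stop("invalid input: record-id intersection is empty")
  m1 <- featureMatrix(e1)[shared, , drop = FALSE]
  m2 <- featureMatrix(e2)[shared, , drop = FALSE]
  labels <- labels[shared]
  if (anyNA(labels)) stop("invalid input: labels missing for some records")
  if (length(shared) < k)
    stop(sprintf("invalid parameter: n = %d < k = %d folds",
                 length(shared), k))
  if (length(unique(labels)) < 2L)
    stop("invalid input: both classes must be present")
  parts <- .make_partitions(shared, labels, k, repeats, seed)
  list(.run_cv(m1, labels, parts, classifier, seed, e1@spec),
       .run_cv(m2, labels, parts, classifier, seed, e2@spec))
}

# confusion counts -> the five metrics, with the zero-denominator
# conventions: undefined fractions are 0, except F1 = 1 when there are no
# positives in truth and none predicted
.fold_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec  <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- if (tp + fn == 0 && tp + fp == 0) 1
        else if (prec + rec == 0) 0
        else 2 * prec * rec / (prec + rec)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  c(F1 = f1, MCC = mcc, precision = prec, recall = rec, specificity = spec)
}

#' Per-fold performance metrics of a CV result
#'
#' F1-score, Matthews correlation coefficient, precision, recall
#' (sensitivity) and specificity, computed per fold row from the
#' thresholded predictions.
#'
#' @param cv A [CVResult-class].
#' @return \code{data.frame} with columns \code{spec}, \code{repetition},
#'   \code{fold} and the five metrics, one row per fold row.
#' @export
computeMetrics <- function(cv) {
  rows <- lapply(foldRecords(cv), function(f)
    data.frame(spec = specId(cv@spec), repetition = f$repetition,
               fold = f$fold, t(.fold_metrics(f$truth, f$pred))))
  do.call(rbind, rows)
}

#' Serialize metric tables to long-format CSV
#'
#' @param metrics A metric table from [computeMetrics()] (or several
#'   row-bound together).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsCsv <- function(metrics, path) {
  long <- stats::reshape(
    metrics, direction = "long",
    varying = c("F1", "MCC", "precision", "recall", "specificity"),
    v.names = "value", timevar = "metric",
    times = c("F1", "MCC", "precision", "recall", "specificity"))
  long <- long[order(long$spec, long$repetition, long$fold),
               c("spec", "repetition", "fold", "metric", "value")]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
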