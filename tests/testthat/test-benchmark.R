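# Cross-validation harness, paired two-group CV and performance metrics.

bench_data <- function(n = 40, seed = 3) {
  d <- generateSyntheticDataset(n, 0.5, lengthRange = c(10L, 30L),
                                seed = seed)
  list(d = d, e = encodeDataset(d, "aac"), labels = classLabels(d))
}

test_that("k folds x repeats rows, stratified within one of proportion", {
  b <- bench_data()
  cv <- repeatedStratifiedCV(b$e, b$labels, k = 5L, repeats = 10L,
                             seed = 1L, classifier = centroidClassifier())
  expect_s4_class(cv, "CVResult")
  expect_length(foldRecords(cv), 50L)
  for (f in foldRecords(cv)) {
    expect_length(f$truth, length(f$ids))
    expect_true(all(f$prob >= 0 & f$prob <= 1))
    # 20/20 labels, k = 5 -> 4 per class per fold
    expect_equal(sum(f$truth == 1), 4)
  }
  # each repetition's test folds partition the ids exactly
  for (r in 1:10) {
    ids <- unlist(lapply(Filter(function(f) f$repetition == r,
                                foldRecords(cv)), `[[`, "ids"))
    expect_setequal(ids, recordIds(b$e))
    expect_equal(anyDuplicated(ids), 0L)
  }
})

test_that("invalid CV setups error before any work", {
  b <- bench_data(n = 4)
  expect_error(repeatedStratifiedCV(b$e, b$labels, k = 5L),
               "invalid parameter")
  one_class <- setNames(rep(1L, length(b$labels)), names(b$labels))
  expect_error(repeatedStratifiedCV(b$e, one_class, k = 2L),
               "invalid input")
})

test_that("same seed gives byte-identical results", {
  b <- bench_data()
  cl <- centroidClassifier()
  cv1 <- repeatedStratifiedCV(b$e, b$labels, k = 5L, repeats = 2L,
                              seed = 7L, classifier = cl)
  cv2 <- repeatedStratifiedCV(b$e, b$labels, k = 5L, repeats = 2L,
                              seed = 7L, classifier = cl)
  expect_identical(foldRecords(cv1), foldRecords(cv2))
  cv3 <- repeatedStratifiedCV(b$e, b$labels, k = 5L, repeats = 2L,
                              seed = 8L, classifier = cl)
  expect_false(identical(foldRecords(cv1), foldRecords(cv3)))
  # the random-forest default is seed-reproducible too
  cv4 <- repeatedStratifiedCV(b$e, b$labels, k = 2L, repeats = 1L,
                              seed = 7L, classifier = rfClassifier(50))
  cv5 <- repeatedStratifiedCV(b$e, b$labels, k = 2L, repeats = 1L,
                              seed = 7L, classifier = rfClassifier(50))
  expect_identical(foldRecords(cv4), foldRecords(cv5))
})

test_that("paired CV reduces to the id intersection with shared folds", {
  b <- bench_data()
  sub <- b$d[recordIds(b$d)[-(1:4)]]
  e2 <- encodeDataset(sub, "gaac")
  res <- pairedTwoGroupCV(b$e, e2, b$labels, k = 5L, repeats = 2L,
                          seed = 2L, classifier = centroidClassifier())
  f1 <- foldRecords(res[[1]])
  f2 <- foldRecords(res[[2]])
  expect_length(f1, 10L)
  for (i in seq_along(f1)) {
    expect_identical(f1[[i]]$ids, f2[[i]]$ids)
    expect_identical(f1[[i]]$truth, f2[[i]]$truth)
    expect_false(any(recordIds(b$d)[1:4] %in% f1[[i]]$ids))
  }
  # disjoint ids error
  other <- generateSyntheticDataset(10, 0.5, lengthRange = c(5L, 10L),
                                    seed = 99, name = "other")
  e3 <- encodeDataset(other, "aac")
  expect_error(pairedTwoGroupCV(b$e, e3, b$labels), "intersection")
})

test_that("metrics match hand-computed confusion values", {
  # one fold row: TP=2 FP=1 FN=1 TN=6
  truth <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  pred  <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  cv <- new("CVResult", spec = encodingSpec("aac"),
            folds = list(list(repetition = 1L, fold = 1L,
                              ids = paste0("r", 1:10), truth = truth,
                              prob = pred, pred = pred)))
  m <- computeMetrics(cv)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$F1, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
  expect_equal(m$MCC,
               (2 * 6 - 1 * 1) / sqrt((2 + 1) * (2 + 1) * (6 + 1) * (6 + 1)))
})

test_that("metric edge conventions: perfect, all-negative, no positives", {
  mk <- function(truth, pred) {
    cv <- new("CVResult", spec = encodingSpec("aac"),
              folds = list(list(repetition = 1L, fold = 1L,
                                ids = paste0("r", seq_along(truth)),
                                truth = truth, prob = pred, pred = pred)))
    computeMetrics(cv)
  }
  perfect <- mk(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(perfect[, c("F1", "MCC", "precision", "recall",
                                  "specificity")]),
               c(F1 = 1, MCC = 1, precision = 1, recall = 1,
                 specificity = 1))
  allneg <- mk(c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_equal(allneg$recall, 0)
  expect_equal(allneg$F1, 0)
  expect_equal(allneg$MCC, 0)
  nopos <- mk(c(0, 0, 0), c(0, 0, 0))
  expect_equal(nopos$F1, 1)  # nothing to find, nothing claimed
})

test_that("composition bias is recoverable above a permuted control", {
  d <- generateSyntheticDataset(60, 0.5, lengthRange = c(10L, 40L),
                                biasStrength = 0.3, seed = 21)
  e <- encodeDataset(d, "aac")
  labels <- classLabels(d)
  cv <- repeatedStratifiedCV(e, labels, k = 5L, repeats = 2L, seed = 1L,
                             classifier = centroidClassifier())
  set.seed(123)
  shuffled <- setNames(sample(unname(labels)), names(labels))
  cvp <- repeatedStratifiedCV(e, shuffled, k = 5L, repeats = 2L, seed = 1L,
                              classifier = centroidClassifier())
  expect_gt(mean(computeMetrics(cv)$F1), mean(computeMetrics(cvp)$F1))
})

test_that("metric tables serialize to long CSV", {
  b <- bench_data(n = 20)
  cv <- repeatedStratifiedCV(b$e, b$labels, k = 2L, repeats = 1L,
                             seed = 1L, classifier = centroidClassifier())
  p <- withr::local_tempfile(fileext = ".csv")
  writeMetricsCsv(computeMetrics(cv), p)
  long <- read.csv(p)
  expect_identical(colnames(long),
                   c("spec", "repetition", "fold", "metric", "value"))
  expect_equal(nrow(long), 2 * 5)
})
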