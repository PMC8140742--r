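# Statistical comparison layer: classifier-output similarity, Friedman /
# Iman-Davenport / Nemenyi critical-difference testing, adjusted RV matrix
# correlation, Davies-Bouldin class separation, and cross-dataset group
# ranking with UPGMA clustering.

#' Disagreement between two binary classifier outputs
#'
#' The fraction of cases on which the two outputs differ,
#' \eqn{(1/n) \sum_k |o_i[k] - o_j[k]|}; a diversity measure for
#' classifier pairs.
#'
#' @param oi,oj Binary (0/1) vectors of equal length.
#' @return Value in [0, 1].
#' @export
#' @examples
#' disagreement(c(1, 0, 1, 1), c(1, 1, 0, 1))
disagreement <- function(oi, oj) {
  if (length(oi) != length(oj)) stop("invalid input: length mismatch")
  if (length(oi) < 1L) stop("invalid input: empty vectors")
  mean(abs(oi - oj))
}

#' Phi coefficient of two binary classifier outputs
#'
#' Standard 2x2 Pearson correlation of the agreement contingency table.
#' Undefined when either vector is constant; in that case \code{NA} is
#' returned with a warning rather than a silent 0.
#'
#' @param oi,oj Binary (0/1) vectors of equal length.
#' @return Value in [-1, 1], or \code{NA} if undefined.
#' @export
phiCoefficient <- function(oi, oj) {
  if (length(oi) != length(oj)) stop("invalid input: length mismatch")
  a <- sum(oi == 1 & oj == 1)
  b <- sum(oi == 1 & oj == 0)
  c_ <- sum(oi == 0 & oj == 1)
  d <- sum(oi == 0 & oj == 0)
  den <- sqrt(a + b) * sqrt(c_ + d) * sqrt(a + c_) * sqrt(b + d)
  if (den == 0) {
    warning("phi undefined: a constant vector")
    return(NA_real_)
  }
  (a * d - b * c_) / den
}

#' Pairwise similarity of paired cross-validation results
#'
#' Computes the chosen similarity for each fold row of each result pair and
#' averages across rows. All results must stem from the same fold
#' partitions (see [pairedTwoGroupCV()]), so the k-th row of every result
#' covers the same held-out records.
#'
#' @param cvResults List of [CVResult-class] with identical fold
#'   partitions.
#' @param measure \code{"disagreement"} or \code{"phi"}.
#' @return Symmetric matrix (spec ids as dimnames) with attribute
#'   \code{measure}.
#' @export
pairwiseSimilarity <- function(cvResults,
                               measure = c("disagreement", "phi")) {
  measure <- match.arg(measure)
  m <- length(cvResults)
  ids <- vapply(cvResults, function(cv) specId(cv@spec), character(1))
  folds <- lapply(cvResults, foldRecords)
  nf <- unique(lengths(folds))
  if (length(nf) != 1L)
    stop("invalid input: results have differing fold-row counts (unpaired)")
  for (r in seq_len(nf)) {
    ref <- folds[[1]][[r]]$ids
    for (j in seq_len(m))
      if (!identical(folds[[j]][[r]]$ids, ref))
        stop("invalid input: fold partitions differ across results (unpaired)")
  }
  fn <- if (measure == "disagreement") disagreement else phiCoefficient
  S <- matrix(if (measure == "disagreement") 0 else 1, m, m,
              dimnames = list(ids, ids))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j <= i) next
    vals <- vapply(seq_len(nf), function(r)
      suppressWarnings(fn(folds[[i]][[r]]$pred, folds[[j]][[r]]$pred)),
      numeric(1))
    S[i, j] <- S[j, i] <- mean(vals, na.rm = TRUE)
  }
  attr(S, "measure") <- measure
  S
}

#' Rank matrix from a per-fold metric matrix
#'
#' @param metricByFold Numeric matrix, folds in rows and models in
#'   columns, holding one performance metric (higher = better).
#' @return Matrix of the same shape with per-fold ranks (rank 1 = best;
#'   ties get average ranks).
#' @export
rankMatrix <- function(metricByFold) {
  t(apply(metricByFold, 1L, function(x) rank(-x, ties.method = "average")))
}

#' Friedman chi-square statistic over a rank matrix
#'
#' \eqn{\chi^2_F = 12N/(k(k+1)) [\sum_j R_j^2 - k(k+1)^2/4]} with
#' \eqn{R_j} the models' average ranks over the \eqn{N} folds.
#'
#' @param ranks Rank matrix (folds x models), e.g. from [rankMatrix()].
#' @return The chi-square value (>= 0; 0 iff all average ranks equal).
#' @export
friedmanStatistic <- function(ranks) {
  N <- nrow(ranks); k <- ncol(ranks)
  if (N < 2L || k < 2L)
    stop("invalid input: need at least 2 folds and 2 models")
  Rj <- colMeans(ranks)
  12 * N / (k * (k + 1)) * (sum(Rj^2) - k * (k + 1)^2 / 4)
}

#' Iman-Davenport correction of the Friedman statistic
#'
#' \eqn{F_F = (N-1)\chi^2_F / (N(k-1) - \chi^2_F)}, F-distributed with
#' \eqn{(k-1)} and \eqn{(k-1)(N-1)} degrees of freedom.
#'
#' @param chi2 Friedman chi-square value.
#' @param N Number of folds.
#' @param k Number of models.
#' @return List with \code{statistic}, \code{df1}, \code{df2} and
#'   \code{p.value}. A non-positive denominator (all folds perfectly
#'   concordant) yields \code{statistic = Inf} with a warning.
#' @export
imanDavenport <- function(chi2, N, k) {
  den <- N * (k - 1) - chi2
  if (den <= 0) {
    warning("degenerate case: N(k-1) - chi2 <= 0, statistic unbounded")
    f <- Inf
  } else {
    f <- (N - 1) * chi2 / den
  }
  df1 <- k - 1
  df2 <- (k - 1) * (N - 1)
  list(statistic = f, df1 = df1, df2 = df2,
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Nemenyi critical difference
#'
#' \eqn{CD = q_\alpha \sqrt{k(k+1)/(6N)}}; two models differ significantly
#' if their average ranks differ by at least \eqn{CD}. The critical value
#' \eqn{q_\alpha} derives from the Studentized range distribution with
#' \eqn{k(N-1)} degrees of freedom, divided by \eqn{\sqrt 2}.
#'
#' @param k Number of models (2..20).
#' @param N Number of folds.
#' @param alpha Significance level, 0.05 or 0.10.
#' @return The critical difference.
#' @export
nemenyiCD <- function(k, N, alpha = 0.05) {
  if (k < 2L || k > 20L)
    stop("unsupported parameter: k must lie in 2..20")
  if (!alpha %in% c(0.05, 0.10))
    stop("unsupported parameter: alpha must be 0.05 or 0.10")
  q <- stats::qtukey(1 - alpha, nmeans = k, df = k * (N - 1)) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * N))
}

#' Flag significantly different model pairs by critical difference
#'
#' @param ranks Rank matrix (folds x models) with model column names.
#' @param alpha Significance level for [nemenyiCD()].
#' @return \code{data.frame} with columns \code{model1}, \code{model2},
#'   \code{rank_diff}, \code{cd}, \code{significant}.
#' @export
criticalDifferencePairs <- function(ranks, alpha = 0.05) {
  k <- ncol(ranks); N <- nrow(ranks)
  cd <- nemenyiCD(k, N, alpha)
  Rj <- colMeans(ranks)
  ids <- colnames(ranks)
  if (is.null(ids)) ids <- paste0("m", seq_len(k))
  pairs <- utils::combn(k, 2L)
  data.frame(
    model1 = ids[pairs[1, ]], model2 = ids[pairs[2, ]],
    rank_diff = abs(Rj[pairs[1, ]] - Rj[pairs[2, ]]),
    cd = cd,
    significant = abs(Rj[pairs[1, ]] - Rj[pairs[2, ]]) >= cd,
    row.names = NULL)
}

#' Adjusted squared Pearson correlation of two feature vectors
#'
#' \eqn{r^2_{adj} = 1 - (n-1)/(n-2) (1 - r^2)}, the small-sample-corrected
#' squared correlation underlying the adjusted RV-coefficient.
#'
#' @param x,y Numeric vectors of equal length \eqn{n \ge 3}.
#' @return The adjusted squared correlation; \code{NA} with a warning if a
#'   vector is constant.
#' @export
adjustedR2 <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("invalid input: length mismatch")
  if (n <= 2L) stop("invalid input: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("adjusted r^2 undefined: constant vector")
    return(NA_real_)
  }
  r2 <- stats::cor(x, y)^2
  1 - (n - 1) / (n - 2) * (1 - r2)
}

#' Adjusted RV-coefficient between two encoded matrices
#'
#' Matrix correlation between two multivariate datasets over the same
#' records, corrected for dimension-driven inflation: the sum of adjusted
#' squared correlations between all column pairs of X and Y, normalized by
#' the geometric mean of the within-matrix sums. Zero-variance columns
#' carry no correlation information and are removed before the
#' computation.
#'
#' @param X,Y Numeric matrices with the same row count \eqn{n \ge 3}.
#' @return The adjusted RV-coefficient (\code{rvAdjusted(X, X)} is 1), or
#'   \code{NA} if either matrix has no non-constant column.
#' @export
rvAdjusted <- function(X, Y) {
  if (nrow(X) != nrow(Y)) stop("invalid input: row-count mismatch")
  n <- nrow(X)
  if (n < 3L) stop("invalid input: need n >= 3 rows")
  X <- X[, apply(X, 2L, stats::sd) > 0, drop = FALSE]
  Y <- Y[, apply(Y, 2L, stats::sd) > 0, drop = FALSE]
  if (ncol(X) == 0L || ncol(Y) == 0L) {
    warning("adjusted RV undefined: no non-constant columns")
    return(NA_real_)
  }
  adj <- function(r2) 1 - (n - 1) / (n - 2) * (1 - r2)
  num <- sum(adj(stats::cor(X, Y)^2))
  dx <- sum(adj(stats::cor(X)^2))
  dy <- sum(adj(stats::cor(Y)^2))
  num / sqrt(dx * dy)
}

#' Correlation matrix of the top-k encodings by F1-score
#'
#' Ranks specs by their mean F1 (ties broken by lexicographic spec id),
#' selects the best \code{kTop} and computes all pairwise adjusted
#' RV-coefficients over the corresponding encoded matrices, rows
#' intersected by record id.
#'
#' @param metricTables List of metric tables (from [computeMetrics()]),
#'   parallel to \code{encodedSets}.
#' @param encodedSets List of [EncodedSet-class].
#' @param kTop Number of top specs to correlate.
#' @return Symmetric \code{kTop x kTop} matrix with spec-id dimnames.
#' @export
topKCorrelation <- function(metricTables, encodedSets, kTop) {
  if (length(metricTables) == 0L) stop("invalid input: no metric tables")
  if (length(metricTables) != length(encodedSets))
    stop("invalid input: metric tables and encoded sets must be parallel")
  if (kTop > length(encodedSets))
    stop("invalid input: kTop exceeds the number of specs")
  ids <- vapply(encodedSets, function(e) specId(e@spec), character(1))
  f1 <- vapply(metricTables, function(tab) mean(tab$F1), numeric(1))
  sel <- order(-f1, ids)[seq_len(kTop)]
  mats <- lapply(encodedSets[sel], featureMatrix)
  out <- matrix(1, kTop, kTop, dimnames = list(ids[sel], ids[sel]))
  for (i in seq_len(kTop)) for (j in seq_len(kTop)) {
    if (j <= i) next
    shared <- intersect(rownames(mats[[i]]), rownames(mats[[j]]))
    out[i, j] <- out[j, i] <- rvAdjusted(mats[[i]][shared, , drop = FALSE],
                                         mats[[j]][shared, , drop = FALSE])
  }
  out
}

#' Davies-Bouldin index of the two-class separation
#'
#' Standard Davies-Bouldin index over the two class clusters: euclidean
#' centroids, mean intra-cluster distance as dispersion. Lower values mean
#' better separation (the standard convention).
#'
#' @param features Numeric matrix (records x features).
#' @param classes Binary labels parallel to the rows, both classes with at
#'   least 2 points.
#' @return Non-negative score.
#' @export
daviesBouldin <- function(features, classes) {
  cls <- sort(unique(classes))
  if (length(cls) != 2L) stop("invalid input: exactly two classes required")
  if (any(table(classes) < 2L))
    stop("invalid input: each class needs >= 2 points")
  features <- as.matrix(features)
  cent <- lapply(cls, function(cl)
    colMeans(features[classes == cl, , drop = FALSE]))
  S <- vapply(seq_along(cls), function(i) {
    pts <- features[classes == cls[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2L, cent[[i]])^2)))
  }, numeric(1))
  M <- sqrt(sum((cent[[1]] - cent[[2]])^2))
  if (M == 0) return(Inf)
  mean(c((S[1] + S[2]) / M, (S[2] + S[1]) / M))
}

#' Rank encoder groups across datasets via their best member
#'
#' Each group's score on a dataset is the best (maximum) mean F1 over its
#' member specs; groups are then ranked per dataset (rank 1 = best, ties
#' get average ranks). Group/dataset combinations without any scored
#' member are imputed as score 0 before ranking.
#'
#' @param scores \code{data.frame} with columns \code{dataset},
#'   \code{spec} and \code{f1} (mean F1 of the spec on the dataset).
#' @param grouping Named character vector mapping spec id to group name;
#'   every spec in \code{scores} must be mapped.
#' @return List with \code{scores} (datasets x groups matrix of group
#'   scores) and \code{ranks} (same shape, per-dataset ranks).
#' @export
rankGroups <- function(scores, grouping) {
  unmapped <- setdiff(unique(scores$spec), names(grouping))
  if (length(unmapped) > 0L)
    stop(sprintf("mapping error: unmapped spec(s): %s",
                 paste(unmapped, collapse = ", ")))
  scores$group <- unname(grouping[scores$spec])
  datasets <- sort(unique(scores$dataset))
  groups <- sort(unique(unname(grouping)))
  S <- matrix(0, length(datasets), length(groups),
              dimnames = list(datasets, groups))
  agg <- stats::aggregate(f1 ~ dataset + group, data = scores, FUN = max)
  S[cbind(match(agg$dataset, datasets), match(agg$group, groups))] <- agg$f1
  R <- t(apply(S, 1L, function(x) rank(-x, ties.method = "average")))
  if (length(datasets) == 1L) {
    R <- matrix(R, nrow = 1L, dimnames = dimnames(S))
  }
  list(scores = S, ranks = R)
}

#' UPGMA clustering of a score matrix
#'
#' Average-linkage agglomerative clustering on euclidean distances along
#' the chosen axis of a datasets x groups score matrix.
#'
#' @param scoreMatrix Numeric matrix (e.g. \code{rankGroups()$scores}).
#' @param axis Cluster the \code{"datasets"} (rows) or \code{"groups"}
#'   (columns).
#' @return An \code{hclust} tree with \code{m - 1} merges for \code{m}
#'   items.
#' @export
upgmaCluster <- function(scoreMatrix, axis = c("datasets", "groups")) {
  axis <- match.arg(axis)
  M <- if (axis == "datasets") scoreMatrix else t(scoreMatrix)
  if (nrow(M) < 2L)
    stop("invalid input: need at least 2 items on the clustered axis")
  stats::hclust(stats::dist(M, method = "euclidean"), method = "average")
}

#' Serialize an hclust tree to Newick
#'
#' @param tree An \code{hclust} object, e.g. from [upgmaCluster()].
#' @param path Optional output file; if \code{NULL} the Newick string is
#'   returned.
#' @return The Newick string, invisibly if written to file.
#' @export
treeToNewick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
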