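# Statistical comparison layer against hand/brute-force evaluation.

test_that("disagreement is the mean absolute prediction difference", {
  expect_equal(disagreement(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(disagreement(c(1, 0, 1), c(0, 1, 0)), 1)
  expect_equal(disagreement(c(1, 0, 1, 1), c(1, 1, 0, 1)), 0.5)
  expect_error(disagreement(c(1, 0), c(1)), "length mismatch")
})

test_that("phi matches the closed-form 2x2 formula", {
  expect_equal(phiCoefficient(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(phiCoefficient(c(1, 0, 1, 0), c(0, 1, 0, 1)), -1)
  # a = 4, b = 1, c = 1, d = 4
  oi <- c(rep(1, 5), rep(0, 5))
  oj <- c(rep(1, 4), 0, 1, rep(0, 4))
  expect_equal(phiCoefficient(oi, oj),
               (4 * 4 - 1 * 1) / sqrt(5 * 5 * 5 * 5))
  expect_warning(out <- phiCoefficient(c(1, 1, 1), c(1, 0, 1)),
                 "undefined")
  expect_true(is.na(out))
})

test_that("pairwise similarity averages fold rows and is symmetric", {
  mkcv <- function(group, preds) {
    folds <- lapply(seq_along(preds), function(i)
      list(repetition = 1L, fold = i, ids = paste0("r", 1:4),
           truth = c(1, 1, 0, 0), prob = preds[[i]], pred = preds[[i]]))
    new("CVResult", spec = encodingSpec(group), folds = folds)
  }
  a <- mkcv("aac", list(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  b <- mkcv("gaac", list(c(1, 1, 0, 1), c(1, 0, 1, 1)))  # differs by 1 of 4
  S <- pairwiseSimilarity(list(a, b), "disagreement")
  expect_equal(unname(S["aac", "gaac"]), 0.25)
  expect_identical(S, t(S))
  expect_equal(unname(diag(S)), c(0, 0))
  # self-pairing under phi gives 1 on the diagonal
  Sp <- pairwiseSimilarity(list(a, b), "phi")
  expect_equal(unname(diag(Sp)), c(1, 1))
  # unpaired results are rejected
  c_ <- mkcv("dpc", list(c(1, 0, 1, 0)))
  expect_error(pairwiseSimilarity(list(a, c_)), "unpaired")
})

test_that("friedman statistic matches direct evaluation", {
  # all models tied in every fold
  tied <- matrix(2, nrow = 4, ncol = 3)
  expect_equal(friedmanStatistic(tied), 0)
  # k = 3, N = 4 hand-built table
  ranks <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(1, 2, 3))
  expect_equal(friedmanStatistic(ranks), o_friedman(ranks))
  # hand substitution: R = (1.25, 2, 2.75)
  expect_equal(o_friedman(ranks),
               12 * 4 / (3 * 4) * ((1.25^2 + 2^2 + 2.75^2) - 3 * 16 / 4))
  # column permutation invariance
  expect_equal(friedmanStatistic(ranks[, c(3, 1, 2)]),
               friedmanStatistic(ranks))
  # rank construction: higher metric -> rank 1, ties averaged
  rm <- rankMatrix(rbind(c(0.9, 0.8, 0.8)))
  expect_equal(unname(rm[1, ]), c(1, 2.5, 2.5))
})

test_that("iman-davenport correction follows the F transform", {
  expect_equal(imanDavenport(0, 10, 3)$statistic, 0)
  ranks <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(1, 2, 3))
  chi2 <- o_friedman(ranks)
  idv <- imanDavenport(chi2, 4, 3)
  expect_equal(idv$statistic, (4 - 1) * chi2 / (4 * (3 - 1) - chi2))
  expect_equal(idv$df1, 2)
  expect_equal(idv$df2, 6)
  # chi2 at the N(k-1) boundary is flagged
  expect_warning(out <- imanDavenport(8, 4, 3), "degenerate")
  expect_equal(out$statistic, Inf)
})

test_that("nemenyi CD scales as sqrt(k(k+1)/6N) with tabled q values", {
  # quadrupling N halves the CD (at large N where q is stable)
  cd1 <- nemenyiCD(5, 1000)
  cd4 <- nemenyiCD(5, 4000)
  expect_equal(cd4, cd1 / 2, tolerance = 1e-3)
  # k = 2: the Studentized range with 2 groups is a scaled t statistic,
  # an independent route to the same critical value
  N <- 10
  q2 <- qt(1 - 0.05 / 2, df = 2 * (N - 1)) * sqrt(2)
  expect_equal(nemenyiCD(2, N), q2 / sqrt(2) * sqrt(1 / N),
               tolerance = 1e-6)
  # large-N limit reproduces the standard published constants (alpha 0.05)
  demsar <- c(`2` = 1.960, `3` = 2.343, `4` = 2.569, `5` = 2.728,
              `10` = 3.164)
  for (k in names(demsar)) {
    kk <- as.integer(k)
    q <- nemenyiCD(kk, 1e6) / sqrt(kk * (kk + 1) / (6 * 1e6))
    expect_equal(q, demsar[[k]], tolerance = 1e-3)
  }
  # CD increases with k at fixed N and alpha
  cds <- vapply(2:10, nemenyiCD, numeric(1), N = 50)
  expect_true(all(diff(cds) > 0))
  expect_error(nemenyiCD(25, 10), "unsupported")
  expect_error(nemenyiCD(5, 10, alpha = 0.01), "unsupported")
})

test_that("critical-difference pairs flag |R_j - R_jhat| >= CD", {
  ranks <- cbind(m1 = rep(1, 30), m2 = rep(2, 30), m3 = rep(3, 30))
  out <- criticalDifferencePairs(ranks, alpha = 0.05)
  expect_equal(nrow(out), 3)
  cd <- nemenyiCD(3, 30)
  expect_equal(unique(out$cd), cd)
  expect_identical(out$significant, abs(out$rank_diff) >= cd)
  expect_true(out$significant[out$model1 == "m1" & out$model2 == "m3"])
})

test_that("adjusted r^2 and adjusted RV match brute-force evaluation", {
  x <- c(1, 2, 3, 4)
  expect_equal(adjustedR2(x, 2 * x + 1), 1)
  y <- stats::residuals(lm(c(2, 1, 4, 3) ~ x))
  expect_equal(adjustedR2(x, unname(y)), 1 - (3 / 2) * 1)  # r2 = 0, n = 4
  expect_error(adjustedR2(c(1, 2), c(3, 4)), "n >= 3")
  expect_warning(adjustedR2(c(1, 1, 1), c(1, 2, 3)), "undefined")

  set.seed(31)
  X <- matrix(rnorm(10), 5, 2)
  Y <- matrix(rnorm(15), 5, 3)
  expect_equal(rvAdjusted(X, Y), o_rv_adjusted(X, Y))
  expect_equal(rvAdjusted(X, X), 1)
  expect_equal(rvAdjusted(Y, X), rvAdjusted(X, Y))
  # invariance to per-column affine rescaling
  Y2 <- sweep(sweep(Y, 2, c(2, -3, 0.5), `*`), 2, c(1, 0, -7), `+`)
  expect_equal(rvAdjusted(X, Y2), rvAdjusted(X, Y))
  expect_error(rvAdjusted(X, Y[1:4, ]), "row-count mismatch")
})

test_that("top-k correlation selects by mean F1 and composes rvAdjusted", {
  set.seed(8)
  mats <- list(a = matrix(rnorm(40), 10), b = matrix(rnorm(30), 10),
               c = matrix(rnorm(50), 10))
  encs <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    dimnames(m) <- list(paste0("r", 1:10),
                        paste0("f", seq_len(ncol(m))))
    new("EncodedSet", spec = encodingSpec(nm), mat = m,
        dropped = data.frame(id = character(0), reason = character(0)))
  })
  mets <- lapply(c(0.9, 0.5, 0.7), function(f1)
    data.frame(F1 = rep(f1, 4)))
  top1 <- topKCorrelation(mets, encs, 1L)
  expect_equal(dim(top1), c(1L, 1L))
  expect_identical(rownames(top1), "a")
  expect_equal(top1[1, 1], 1)
  top3 <- topKCorrelation(mets, encs, 3L)
  expect_identical(rownames(top3), c("a", "c", "b"))
  for (i in 1:3) for (j in 1:3) {
    nm_i <- rownames(top3)[i]; nm_j <- rownames(top3)[j]
    expect_equal(top3[i, j],
                 if (i == j) 1 else o_rv_adjusted(mats[[nm_i]],
                                                  mats[[nm_j]]),
                 tolerance = 1e-9)
  }
})

test_that("davies-bouldin follows the standard lower-is-better index", {
  set.seed(5)
  tight_far <- rbind(matrix(rnorm(40, 0, 0.05), 20),
                     matrix(rnorm(40, 10, 0.05), 20))
  y <- rep(c(0, 1), each = 20)
  db <- daviesBouldin(tight_far, y)
  expect_lt(db, 0.1)
  expect_equal(db, o_davies_bouldin(tight_far, y))
  # duplicating every point leaves the index unchanged
  expect_equal(daviesBouldin(rbind(tight_far, tight_far), c(y, y)), db)
  # identical class distributions separate poorly
  overlap <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40), 20))
  expect_gt(daviesBouldin(overlap, y), 5)
  expect_error(daviesBouldin(tight_far, rep(0, 40)), "two classes")
})

test_that("group ranking takes the best member and averages ties", {
  scores <- data.frame(
    dataset = rep(c("d1", "d2"), each = 4),
    spec = rep(c("a1", "a2", "b1", "c1"), 2),
    f1 = c(0.7, 0.9, 0.8, 0.8, 0.5, 0.6, 0.9, 0.4))
  grouping <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C")
  out <- rankGroups(scores, grouping)
  expect_equal(unname(out$scores["d1", ]), c(0.9, 0.8, 0.8))
  expect_equal(unname(out$ranks["d1", ]), c(1, 2.5, 2.5))
  expect_equal(unname(out$ranks["d2", ]), c(2, 1, 3))
  expect_error(rankGroups(scores, grouping[-1]), "mapping error")
  # a single group ranks 1 everywhere
  one <- rankGroups(data.frame(dataset = "d1", spec = "a1", f1 = 0.5),
                    c(a1 = "A"))
  expect_equal(unname(one$ranks[1, 1]), 1)
})

test_that("UPGMA clustering merges closest pairs first", {
  M <- rbind(A = c(0, 0), B = c(1, 0), C = c(10, 0))
  h <- upgmaCluster(M, axis = "datasets")
  expect_equal(length(h$height), 2L)          # m - 1 merges
  first <- rownames(M)[-h$merge[1, ]]
  expect_setequal(first, c("A", "B"))
  expect_equal(h$height[1], 1)
  # average linkage: C joins at mean(d(A,C), d(B,C)) = 9.5
  expect_equal(h$height[2], 9.5)
  # duplicated rows merge at height 0
  M2 <- rbind(A = c(1, 1), B = c(1, 1), C = c(5, 5))
  expect_equal(upgmaCluster(M2)$height[1], 0)
  expect_error(upgmaCluster(M[1, , drop = FALSE]), "at least 2")
  # Newick export carries all leaves
  nwk <- treeToNewick(upgmaCluster(M))
  expect_true(all(vapply(c("A", "B", "C"), grepl, logical(1), x = nwk)))
})
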