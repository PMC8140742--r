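# Encoder behaviour on hand-checkable examples, family identities and
# bookkeeping invariants. (The exhaustive oracle sweep lives in
# test-acceptance.R.)

toy <- function(seqs) {
  names(seqs) <- paste0("p", seq_along(seqs))
  peptideSet(seqs, rep_len(c(1, 0), length(seqs)))
}

feat <- function(e, id, name) featureMatrix(e)[id, name]

test_that("single-letter composition matches direct counting", {
  e <- encodeDataset(toy(c("AAC")), "aac")
  expect_equal(feat(e, "p1", "A"), 2 / 3)
  expect_equal(feat(e, "p1", "C"), 1 / 3)
  expect_equal(sum(featureMatrix(e)), 1)
  e2 <- encodeDataset(toy(c(paste(aminoAcids(), collapse = ""))), "aac")
  expect_equal(unname(featureMatrix(e2)[1, ]), rep(0.05, 20))
})

test_that("dipeptide composition counts overlapping pairs", {
  e <- encodeDataset(toy(c("AAA")), "dpc")
  expect_equal(feat(e, "p1", "AA"), 1)
  expect_equal(sum(featureMatrix(e)), 1)
})

test_that("gapped pair composition enumerates pairs per gap", {
  e0 <- encodeDataset(toy(c("AACA")), encodingSpec("cksaap", gmax = 0L))
  expect_equal(feat(e0, "p1", "g0.AA"), 1 / 3)
  expect_equal(feat(e0, "p1", "g0.AC"), 1 / 3)
  expect_equal(feat(e0, "p1", "g0.CA"), 1 / 3)
  e1 <- encodeDataset(toy(c("AACA")), encodingSpec("cksaap", gmax = 1L))
  # gap-1 pairs: (s1,s3) = AC, (s2,s4) = AA
  expect_equal(feat(e1, "p1", "g1.AC"), 1 / 2)
  expect_equal(feat(e1, "p1", "g1.AA"), 1 / 2)
  e3 <- encodeDataset(toy(c("ACDEFG")), encodingSpec("cksaap", gmax = 3L))
  expect_equal(ncol(featureMatrix(e3)), 1600)
})

test_that("sliding-window composition drops too-short sequences", {
  e <- encodeDataset(toy(c("AAAA")), encodingSpec("eaac", window = 4L))
  expect_equal(unname(featureMatrix(e)[1, "w1.A"]), 1)
  d <- toy(c("AC", "ACDE"))
  e2 <- encodeDataset(d, encodingSpec("eaac", window = 3L))
  expect_identical(droppedRecords(e2)$id, "p1")
  expect_match(droppedRecords(e2)$reason, "window")
  # a pure-group sequence saturates its group feature in every window
  e3 <- encodeDataset(toy(c("GAVLMI")), encodingSpec("egaac", window = 3L))
  expect_true(all(featureMatrix(e3)[, grepl("aliphatic",
                                            colnames(featureMatrix(e3)))] == 1))
})

test_that("autocorrelation encoders follow the classic formulas", {
  kd <- aaIndexTables()$KYTJ820101
  expect_error(encodeDataset(toy(c("ACDC")),
                             encodingSpec("moran", lag = 1L,
                                          indices = list(flat = rep(1, 20)))),
               "zero variance")
  e <- encodeDataset(toy(c("ACDC")),
                     encodingSpec("moran", lag = 1L,
                                  indices = list(kd = kd)))
  expect_equal(unname(featureMatrix(e)[1, ]),
               o_autocorr("ACDC", "moran", 1, kd))
  # identical residues: standardized value v gives v^2 at every lag
  v <- (kd[["A"]] - mean(kd)) / sd(kd)
  e2 <- encodeDataset(toy(c("AAAAAA")),
                      encodingSpec("nmbroto", lag = 3L,
                                   indices = list(kd = kd)))
  expect_equal(unname(featureMatrix(e2)[1, ]), rep(v^2, 3))
})

test_that("CTD descriptors count classes, transitions and landmarks", {
  # polyR is entirely in class 1 of the hydrophobicity partition
  e <- encodeDataset(toy(c("RRRR")), "ctdc")
  expect_equal(unname(featureMatrix(e)[1, paste0("hydrophobicity.g",
                                                 1:3)]), c(1, 0, 0))
  # R,R,G,G: one polar->neutral change among 3 adjacent pairs
  e2 <- encodeDataset(toy(c("RRGG")), "ctdt")
  expect_equal(unname(featureMatrix(e2)[1, "hydrophobicity.t12"]), 1 / 3)
  # class present only at the last residue of a length-10 sequence
  e3 <- encodeDataset(toy(c("RRRRRRRRRC")), "ctdd")
  cw <- paste0("hydrophobicity.g3.", c("first", "p25", "p50", "p75",
                                       "p100"))
  expect_equal(unname(featureMatrix(e3)[1, cw]), rep(100, 5))
})

test_that("conjoint triads use the 7-class alphabet and length rule", {
  e <- encodeDataset(toy(c("AAAA")), "ctriad")
  m <- featureMatrix(e)
  expect_equal(sum(m), 1)          # single triad carries all mass
  expect_equal(ncol(m), 343)
  d <- toy(c("ACDK", "ACDKACDK"))
  e2 <- encodeDataset(d, encodingSpec("ksctriad", kmax = 1L))
  expect_identical(droppedRecords(e2)$id, "p1")   # needs 2k+3 = 5
  e3 <- encodeDataset(toy(c("ACDKACDKA")), encodingSpec("ksctriad",
                                                        kmax = 2L))
  expect_equal(ncol(featureMatrix(e3)), 1029)
})

test_that("sequence-order encoders honor the distance matrices", {
  # identical residues: zero diagonal makes all coupling numbers 0
  e <- encodeDataset(toy(c("AAAAA")), encodingSpec("socnumber", nlag = 2L))
  expect_equal(unname(featureMatrix(e)[1, ]), rep(0, 4))
  # qsorder with zero couplings: first-20 block is the pure composition
  e2 <- encodeDataset(toy(c("AAAAA")), encodingSpec("qsorder", nlag = 2L,
                                                    weight = 0.3))
  m <- featureMatrix(e2)
  expect_equal(unname(m[1, "grantham.A"]), 1)
  expect_equal(sum(m[1, grepl("grantham", colnames(m))]), 1)
  d <- toy(c("ACD", "ACDEFGH"))
  e3 <- encodeDataset(d, encodingSpec("socnumber", nlag = 3L))
  expect_identical(droppedRecords(e3)$id, "p1")
})

test_that("pseudo amino-acid composition sums to 1 and limits to aac", {
  d <- toy(c("ACDKACDKLM", "KKKKRRRRAA"))
  for (v in c("paac", "apaac")) {
    e <- encodeDataset(d, encodingSpec(v, lam = 2L, weight = 0.05))
    expect_equal(unname(rowSums(featureMatrix(e))), c(1, 1))
  }
  e0 <- encodeDataset(d, encodingSpec("paac", lam = 2L, weight = 0))
  aacm <- featureMatrix(encodeDataset(d, "aac"))
  expect_equal(unname(featureMatrix(e0)[, 1:20]), unname(aacm))
})

test_that("too-short sequences for lambda are dropped", {
  d <- toy(c("ACD", "ACDEFGHIKL"))
  e <- encodeDataset(d, encodingSpec("paac", lam = 4L))
  expect_identical(droppedRecords(e)$id, "p1")
  expect_error(encodeDataset(toy(c("ACD")), encodingSpec("paac", lam = 5L)),
               "empty encoding")
})

test_that("reduced-alphabet k-tuples match direct enumeration", {
  # 2-cluster reduction, 2-tuples on an alternating pattern
  d <- toy(c("CACA"))  # C hydrophobic cluster, A polar cluster under size 2
  e <- encodeDataset(d, encodingSpec("psekraac", clusters = 2L,
                                     ktuple = 2L, gap = 0L))
  expect_equal(unname(featureMatrix(e)[1, ]),
               o_psekraac("CACA", reducedAlphabet(2), 2, 0))
  e5 <- encodeDataset(d, encodingSpec("psekraac", clusters = 5L,
                                      ktuple = 2L, gap = 0L))
  expect_equal(ncol(featureMatrix(e5)), 25)
})

test_that("per-residue encoders need aligned input and encode gaps as 0", {
  d <- toy(c("AC", "CA"))
  e <- encodeDataset(d, "binary")
  m <- featureMatrix(e)
  expect_equal(ncol(m), 40)
  expect_equal(sum(m["p1", ]), 2)
  expect_equal(unname(m["p1", c("p1.A", "p2.C")]), c(1, 1))
  ragged <- toy(c("AC", "ACD"))
  expect_error(encodeDataset(ragged, "binary"), "alignment required")
  ga <- peptideSet(c(x = "A-C", y = "ACC"), c(1, 0), aligned = TRUE)
  mg <- featureMatrix(encodeDataset(ga, "binary"))
  expect_equal(sum(mg["x", grepl("^p2\\.", colnames(mg))]), 0)
})

test_that("chaos-game grid conserves counts and converges on one symbol", {
  d <- toy(c("ACDKACDKAC"))
  e <- encodeDataset(d, encodingSpec("fcgr", resolution = 4L))
  expect_equal(sum(featureMatrix(e)), 1)   # counts / length sum to 1
  # a one-class sequence converges to the class corner cell
  e2 <- encodeDataset(toy(c(strrep("K", 30))),
                      encodingSpec("fcgr", resolution = 2L))
  m2 <- featureMatrix(e2)
  expect_gt(m2[1, which.max(m2[1, ])], 0.9)
})

test_that("family identities hold exactly", {
  d <- toy(c("ACDKACDKLM", "KKKKRRRRAA", "MNPQRSTVWY"))
  aacm <- unname(featureMatrix(encodeDataset(d, "aac")))
  dpcm <- unname(featureMatrix(encodeDataset(d, "dpc")))
  expect_equal(unname(featureMatrix(encodeDataset(
    d, encodingSpec("ngram", n = 1L)))), aacm)
  expect_equal(unname(featureMatrix(encodeDataset(
    d, encodingSpec("ngram", n = 2L)))), dpcm)
  expect_equal(unname(featureMatrix(encodeDataset(
    d, encodingSpec("distance_frequency", bins = 1L)))), aacm)
  expect_equal(unname(featureMatrix(encodeDataset(
    d, encodingSpec("psekraac", clusters = 20L, ktuple = 1L,
                    gap = 0L)))), aacm)
})

test_that("row bookkeeping and determinism hold for every encoder", {
  d <- generateSyntheticDataset(12, 0.5, lengthRange = c(4L, 20L),
                                seed = 11)
  params <- list(eaac = list(window = 3L), egaac = list(window = 3L),
                 moran = list(lag = 2L), geary = list(lag = 2L),
                 nmbroto = list(lag = 2L), socnumber = list(nlag = 2L),
                 qsorder = list(nlag = 2L), paac = list(lam = 2L),
                 apaac = list(lam = 2L))
  skip_groups <- c("binary", "blosum62", "zscale", "aaindex") # need alignment
  for (grp in setdiff(encodingGroups(), skip_groups)) {
    spec <- do.call(encodingSpec, c(list(grp), params[[grp]]))
    e1 <- encodeDataset(d, spec)
    e2 <- encodeDataset(d, spec)
    expect_identical(featureMatrix(e1), featureMatrix(e2), label = grp)
    expect_equal(nrow(featureMatrix(e1)) + nrow(droppedRecords(e1)),
                 length(d), label = grp)
    expect_true(all(recordIds(e1) %in% recordIds(d)), label = grp)
    # row order preserved
    expect_identical(recordIds(e1),
                     intersect(recordIds(d), recordIds(e1)), label = grp)
  }
})
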