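# Independent brute-force oracles: each evaluates an encoding or statistic
# naively (explicit loops, no shared code with the package internals) so
# the optimized implementations can be checked against them.

AA4 <- c("A", "C", "D", "K")  # 4-letter sub-alphabet spanning distinct
                              # physicochemical groups

# all sequences of a given length over an alphabet, as a PeptideSet
exhaustive_dataset <- function(len, alphabet = AA4) {
  seqs <- do.call(paste0, rev(expand.grid(rep(list(alphabet), len),
                                          stringsAsFactors = FALSE)))
  names(seqs) <- sprintf("s%04d", seq_along(seqs))
  peptideSet(seqs, rep_len(c(1, 0), length(seqs)), name = "exhaustive")
}

# ---- composition-family oracles -------------------------------------------

o_kmer <- function(seq, k, alphabet = aminoAcids(), map = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (!is.null(map)) chars <- map[chars]
  kmers <- .o_all_tuples(alphabet, k)
  cnt <- setNames(numeric(length(kmers)), kmers)
  if (length(chars) < k) return(NULL)
  for (i in 1:(length(chars) - k + 1))
    cnt[paste(chars[i:(i + k - 1)], collapse = "")] <-
      cnt[paste(chars[i:(i + k - 1)], collapse = "")] + 1
  unname(cnt / sum(cnt))
}

.o_all_tuples <- function(alphabet, k) {
  out <- alphabet
  while (k > 1) {
    out <- as.vector(t(outer(out, alphabet, paste0)))
    k <- k - 1
  }
  out
}

o_cksaap <- function(seq, gmax, alphabet = aminoAcids(), map = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (!is.null(map)) chars <- map[chars]
  if (length(chars) < gmax + 2) return(NULL)
  pairs <- .o_all_tuples(alphabet, 2)
  out <- c()
  for (g in 0:gmax) {
    cnt <- setNames(numeric(length(pairs)), pairs)
    for (i in 1:(length(chars) - g - 1)) {
      p <- paste0(chars[i], chars[i + g + 1])
      cnt[p] <- cnt[p] + 1
    }
    out <- c(out, unname(cnt / sum(cnt)))
  }
  out
}

o_sliding <- function(seq, w, n_windows, alphabet = aminoAcids(),
                      map = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (!is.null(map)) chars <- map[chars]
  if (length(chars) < w) return(NULL)
  out <- c()
  for (j in seq_len(n_windows)) {
    win <- chars[j:(j + w - 1)]
    out <- c(out, vapply(alphabet, function(a) sum(win == a) / w,
                         numeric(1)))
  }
  out
}

o_distance_frequency <- function(seq, bins) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- c()
  for (a in aminoAcids()) {
    cnt <- numeric(bins)
    for (i in seq_len(L)) {
      if (chars[i] != a) next
      rel <- if (L == 1) 0 else (i - 1) / (L - 1)
      b <- min(floor(rel * bins) + 1, bins)
      cnt[b] <- cnt[b] + 1
    }
    out <- c(out, cnt / L)
  }
  out
}

# ---- CTD and conjoint-triad oracles ---------------------------------------

o_class_of <- function(a, groups) {
  for (g in seq_along(groups))
    if (grepl(a, groups[g], fixed = TRUE)) return(g)
  stop("unmapped residue")
}

o_ctdc <- function(seq, properties) {
  chars <- strsplit(seq, "")[[1]]
  out <- c()
  for (p in properties) {
    cls <- vapply(chars, o_class_of, numeric(1), groups = p)
    out <- c(out, vapply(1:3, function(g) sum(cls == g) / length(cls),
                         numeric(1)))
  }
  out
}

o_ctdt <- function(seq, properties) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 2) return(NULL)
  out <- c()
  for (p in properties) {
    cls <- vapply(chars, o_class_of, numeric(1), groups = p)
    t12 <- t13 <- t23 <- 0
    for (i in 1:(L - 1)) {
      pr <- sort(c(cls[i], cls[i + 1]))
      if (pr[1] == 1 && pr[2] == 2) t12 <- t12 + 1
      if (pr[1] == 1 && pr[2] == 3) t13 <- t13 + 1
      if (pr[1] == 2 && pr[2] == 3) t23 <- t23 + 1
    }
    out <- c(out, c(t12, t13, t23) / (L - 1))
  }
  out
}

o_ctdd <- function(seq, properties) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- c()
  for (p in properties) {
    cls <- vapply(chars, o_class_of, numeric(1), groups = p)
    for (g in 1:3) {
      pos <- which(cls == g)
      if (length(pos) == 0) { out <- c(out, numeric(5)); next }
      N <- length(pos)
      ranks <- pmax(1, c(1, ceiling(0.25 * N), ceiling(0.5 * N),
                         ceiling(0.75 * N), N))
      out <- c(out, pos[ranks] / L * 100)
    }
  }
  out
}

o_conjoint_triad <- function(seq, kmax) {
  classes <- c("AGV", "ILFP", "YMTS", "HNQW", "RK", "DE", "C")
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 2 * kmax + 3) return(NULL)
  cls <- vapply(chars, o_class_of, numeric(1), groups = classes)
  out <- c()
  for (k in 0:kmax) {
    cnt <- numeric(343)
    for (i in 1:(L - 2 * (k + 1))) {
      code <- (cls[i] - 1) * 49 + (cls[i + k + 1] - 1) * 7 +
        cls[i + 2 * (k + 1)]
      cnt[code] <- cnt[code] + 1
    }
    rng <- range(cnt)
    out <- c(out, if (rng[2] > rng[1]) (cnt - rng[1]) / (rng[2] - rng[1])
             else numeric(343))
  }
  out
}

# ---- autocorrelation / order / pseudo-composition oracles -----------------

o_standardize <- function(v) (v - mean(v)) / sd(v)

o_autocorr <- function(seq, variant, lag, index) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L <= lag) return(NULL)
  P <- o_standardize(index)[match(chars, aminoAcids())]
  out <- numeric(lag)
  for (d in seq_len(lag)) {
    if (variant == "nmbroto") {
      out[d] <- sum(P[1:(L - d)] * P[(1 + d):L]) / (L - d)
    } else if (variant == "moran") {
      den <- sum((P - mean(P))^2) / L
      num <- sum((P[1:(L - d)] - mean(P)) * (P[(1 + d):L] - mean(P))) /
        (L - d)
      out[d] <- if (den == 0) 0 else num / den
    } else {
      den <- sum((P - mean(P))^2) / (L - 1)
      num <- sum((P[1:(L - d)] - P[(1 + d):L])^2) / (2 * (L - d))
      out[d] <- if (den == 0) 0 else num / den
    }
  }
  out
}

o_tau <- function(chars, dmat, nlag) {
  L <- length(chars)
  vapply(seq_len(nlag), function(dl) {
    s <- 0
    for (i in 1:(L - dl)) s <- s + dmat[chars[i], chars[i + dl]]^2
    s
  }, numeric(1))
}

o_socnumber <- function(seq, nlag, mats) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) <= nlag) return(NULL)
  unlist(lapply(mats, function(m) o_tau(chars, m, nlag)))
}

o_qsorder <- function(seq, nlag, w, mats) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) <= nlag) return(NULL)
  f <- vapply(aminoAcids(), function(a) sum(chars == a), numeric(1))
  unlist(lapply(mats, function(m) {
    tau <- o_tau(chars, m, nlag)
    den <- sum(f) + w * sum(tau)
    c(unname(f) / den, w * tau / den)
  }))
}

o_paac <- function(seq, lam, w, h1, h2, mass) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L <= lam) return(NULL)
  S <- cbind(o_standardize(h1), o_standardize(h2), o_standardize(mass))
  idx <- match(chars, aminoAcids())
  theta <- numeric(lam)
  for (d in seq_len(lam)) {
    v <- 0
    for (i in 1:(L - d))
      v <- v + mean((S[idx[i], ] - S[idx[i + d], ])^2)
    theta[d] <- v / (L - d)
  }
  f <- vapply(aminoAcids(), function(a) sum(chars == a) / L, numeric(1))
  den <- 1 + w * sum(theta)
  c(unname(f) / den, w * theta / den)
}

o_apaac <- function(seq, lam, w, h1, h2) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L <= lam) return(NULL)
  H <- cbind(o_standardize(h1), o_standardize(h2))
  idx <- match(chars, aminoAcids())
  tau <- numeric(2 * lam)
  for (d in seq_len(lam)) {
    for (j in 1:2) {
      v <- 0
      for (i in 1:(L - d)) v <- v + H[idx[i], j] * H[idx[i + d], j]
      tau[2 * (d - 1) + j] <- v / (L - d)
    }
  }
  f <- vapply(aminoAcids(), function(a) sum(chars == a) / L, numeric(1))
  den <- 1 + w * sum(tau)
  c(unname(f) / den, w * tau / den)
}

o_psekraac <- function(seq, groups, t, g) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  span <- (t - 1) * (g + 1) + 1
  if (L < span) return(NULL)
  cls <- vapply(chars, o_class_of, numeric(1), groups = groups)
  n <- length(groups)
  cnt <- numeric(n^t)
  for (i in 1:(L - span + 1)) {
    code <- 0
    for (s in 0:(t - 1)) code <- code * n + (cls[i + s * (g + 1)] - 1)
    cnt[code + 1] <- cnt[code + 1] + 1
  }
  cnt / sum(cnt)
}

# ---- per-residue and chaos-game oracles -----------------------------------

o_per_residue <- function(seq, block_fn, width) {
  chars <- strsplit(seq, "")[[1]]
  out <- c()
  for (a in chars) out <- c(out, if (a == "-") numeric(width)
                            else block_fn(a))
  out
}

o_fcgr <- function(seq, res, groups) {
  chars <- strsplit(seq, "")[[1]]
  corners <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  pt <- c(0.5, 0.5)
  grid <- matrix(0, res, res)
  for (a in chars) {
    g <- o_class_of(a, groups)
    pt <- (pt + corners[[g]]) / 2
    cx <- min(floor(pt[1] * res) + 1, res)
    cy <- min(floor(pt[2] * res) + 1, res)
    grid[cy, cx] <- grid[cy, cx] + 1
  }
  out <- c()
  for (r in 1:res) out <- c(out, grid[r, ])
  out / length(chars)
}

# ---- statistics oracles ---------------------------------------------------

o_rv_adjusted <- function(X, Y) {
  n <- nrow(X)
  adj <- function(x, y) 1 - (n - 1) / (n - 2) * (1 - cor(x, y)^2)
  num <- 0
  for (i in seq_len(ncol(X))) for (j in seq_len(ncol(Y)))
    num <- num + adj(X[, i], Y[, j])
  dx <- 0
  for (i in seq_len(ncol(X))) for (j in seq_len(ncol(X)))
    dx <- dx + adj(X[, i], X[, j])
  dy <- 0
  for (i in seq_len(ncol(Y))) for (j in seq_len(ncol(Y)))
    dy <- dy + adj(Y[, i], Y[, j])
  num / sqrt(dx * dy)
}

o_friedman <- function(ranks) {
  N <- nrow(ranks); k <- ncol(ranks)
  Rj <- numeric(k)
  for (j in seq_len(k)) Rj[j] <- sum(ranks[, j]) / N
  12 * N / (k * (k + 1)) * (sum(Rj^2) - k * (k + 1)^2 / 4)
}

o_davies_bouldin <- function(X, y) {
  cls <- sort(unique(y))
  cent <- lapply(cls, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  S <- vapply(seq_along(cls), function(i) {
    pts <- X[y == cls[i], , drop = FALSE]
    mean(apply(pts, 1, function(p) sqrt(sum((p - cent[[i]])^2))))
  }, numeric(1))
  db <- 0
  for (i in seq_along(cls)) {
    best <- -Inf
    for (j in seq_along(cls)) {
      if (j == i) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (S[i] + S[j]) / M)
    }
    db <- db + best
  }
  db / length(cls)
}

# label-permutation control with a fixed seed
permuted_labels <- function(labels, seed) {
  set.seed(seed + 10000)
  setNames(sample(unname(labels)), names(labels))
}

# ---- shared harness -------------------------------------------------------

# run an encoder over exhaustive datasets and compare every retained row
# (and the drop set) with the oracle
check_encoder_oracle <- function(group, params, oracle, lengths = 1:6,
                                 alphabet = AA4, tol = 1e-10) {
  for (len in lengths) {
    d <- exhaustive_dataset(len, alphabet)
    enc <- tryCatch(
      do.call(encodeDataset, list(d, do.call(encodingSpec,
                                             c(list(group), params)))),
      error = function(e) e)
    seqs <- sequences(d)
    expected <- lapply(seqs, oracle)
    keep <- !vapply(expected, is.null, logical(1))
    if (!any(keep)) {
      expect_true(inherits(enc, "error") ||
                    nrow(featureMatrix(enc)) == 0,
                  label = sprintf("%s len %d: all dropped", group, len))
      next
    }
    expect_false(inherits(enc, "error"),
                 label = sprintf("%s len %d encodes", group, len))
    M <- featureMatrix(enc)
    expect_identical(rownames(M), names(seqs)[keep],
                     label = sprintf("%s len %d drop set", group, len))
    O <- do.call(rbind, expected[keep])
    expect_equal(unname(M), unname(O), tolerance = tol,
                 label = sprintf("%s len %d values", group, len))
  }
}
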