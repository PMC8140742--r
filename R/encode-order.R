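# Sequence-order descriptors (coupling numbers and quasi-sequence-order)
# and Chou-style pseudo amino-acid composition (plain and amphiphilic),
# plus the reduced-alphabet gapped k-tuple encoder.

# default distance matrices for the sequence-order encoders
.order_matrices <- function() {
  list(grantham = granthamDistance(), physchem = physchemDistance())
}

# tau_d = sum_i dist(a_i, a_{i+d})^2 for d = 1..nlag
.coupling_numbers <- function(chars, dmat, nlag) {
  L <- length(chars)
  vapply(seq_len(nlag), function(dl) {
    i <- seq_len(L - dl)
    sum(dmat[cbind(chars[i], chars[i + dl])]^2)
  }, numeric(1))
}

.encode_socnumber <- function(d, params, spec) {
  nlag <- as.integer(params$nlag)
  if (nlag < 1L) stop("invalid parameter: nlag must be >= 1")
  mats <- params$matrices
  feature_names <- unlist(lapply(names(mats), function(m)
    paste0(m, ".tau", seq_len(nlag))))
  .encode_per_sequence(d, spec, feature_names, function(chars) {
    L <- length(chars)
    if (L <= nlag) return(sprintf("sequence length %d <= nlag %d", L, nlag))
    unlist(lapply(mats, .coupling_numbers, chars = chars, nlag = nlag))
  })
}

# quasi-sequence-order: per distance matrix, occurrence counts f_a and
# couplings tau_d combined as f_a / (sum f + w sum tau) and
# w tau_d / (sum f + w sum tau)
.encode_qsorder <- function(d, params, spec) {
  nlag <- as.integer(params$nlag)
  w <- params$weight
  if (nlag < 1L) stop("invalid parameter: nlag must be >= 1")
  if (w <= 0) stop("invalid parameter: weight must be positive")
  mats <- params$matrices
  aa <- aminoAcids()
  feature_names <- unlist(lapply(names(mats), function(m)
    c(paste0(m, ".", aa), paste0(m, ".tau", seq_len(nlag)))))
  .encode_per_sequence(d, spec, feature_names, function(chars) {
    L <- length(chars)
    if (L <= nlag) return(sprintf("sequence length %d <= nlag %d", L, nlag))
    f <- tabulate(match(chars, aa), nbins = 20L)
    unlist(lapply(mats, function(dmat) {
      tau <- .coupling_numbers(chars, dmat, nlag)
      den <- sum(f) + w * sum(tau)
      c(f / den, w * tau / den)
    }))
  })
}

# squared-difference correlation of the three standardized scales
.paac_theta <- function(P, dlag) {
  L <- nrow(P)
  i <- seq_len(L - dlag)
  mean(rowMeans((P[i, , drop = FALSE] - P[i + dlag, , drop = FALSE])^2))
}

.paac_scales <- function() {
  cbind(h1 = .standardize_index(.scale_hydrophobicity, "hydrophobicity"),
        h2 = .standardize_index(.scale_hydrophilicity, "hydrophilicity"),
        m  = .standardize_index(.scale_sidechain_mass, "mass"))
}

.encode_paac <- function(d, params, spec) {
  lam <- as.integer(params$lam)
  w <- params$weight
  if (lam < 1L) stop("invalid parameter: lam must be >= 1")
  if (w < 0) stop("invalid parameter: weight must be non-negative")
  S <- .paac_scales()
  aa <- aminoAcids()
  feature_names <- c(aa, paste0("theta", seq_len(lam)))
  .encode_per_sequence(d, spec, feature_names, function(chars) {
    L <- length(chars)
    if (L <= lam) return(sprintf("sequence length %d <= lambda %d", L, lam))
    idx <- match(chars, aa)
    P <- S[idx, , drop = FALSE]
    theta <- vapply(seq_len(lam), function(dl) .paac_theta(P, dl),
                    numeric(1))
    f <- tabulate(idx, nbins = 20L) / L
    den <- 1 + w * sum(theta)
    c(f / den, w * theta / den)
  })
}

# amphiphilic variant: separate hydrophobicity and hydrophilicity
# correlation factors, tau_{2d-1} and tau_{2d}
.encode_apaac <- function(d, params, spec) {
  lam <- as.integer(params$lam)
  w <- params$weight
  if (lam < 1L) stop("invalid parameter: lam must be >= 1")
  if (w < 0) stop("invalid parameter: weight must be non-negative")
  S <- .paac_scales()[, c("h1", "h2")]
  aa <- aminoAcids()
  feature_names <- c(aa, paste0("tau", seq_len(2L * lam)))
  .encode_per_sequence(d, spec, feature_names, function(chars) {
    L <- length(chars)
    if (L <= lam) return(sprintf("sequence length %d <= lambda %d", L, lam))
    idx <- match(chars, aa)
    H <- S[idx, , drop = FALSE]
    tau <- numeric(2L * lam)
    for (dl in seq_len(lam)) {
      i <- seq_len(L - dl)
      tau[2L * dl - 1L] <- sum(H[i, 1] * H[i + dl, 1]) / (L - dl)
      tau[2L * dl]      <- sum(H[i, 2] * H[i + dl, 2]) / (L - dl)
    }
    f <- tabulate(idx, nbins = 20L) / L
    den <- 1 + w * sum(tau)
    c(f / den, w * tau / den)
  })
}

# gapped k-tuple frequencies over a bundled reduced alphabet; tuple
# positions are i, i+g+1, ..., i+(t-1)(g+1)
.encode_psekraac <- function(d, params, spec) {
  clusters <- as.integer(params$clusters)
  t <- as.integer(params$ktuple)
  g <- as.integer(params$gap)
  if (t < 1L) stop("invalid parameter: ktuple must be >= 1")
  if (g < 0L) stop("invalid parameter: gap must be >= 0")
  groups <- reducedAlphabet(clusters)
  map <- .partition_map(groups)
  alphabet <- if (clusters == 20L) aminoAcids() else
    paste0("r", seq_len(clusters))
  feature_names <- .kmer_names(alphabet, t)
  span <- (t - 1L) * (g + 1L) + 1L
  .encode_per_sequence(d, spec, feature_names, function(chars) {
    L <- length(chars)
    if (L < span)
      return(sprintf("sequence shorter than tuple span %d", span))
    idx <- unname(map[chars])
    i <- seq_len(L - span + 1L)
    tup <- vapply(seq_len(t) - 1L, function(s) idx[i + s * (g + 1L)],
                  integer(length(i)))
    if (length(i) == 1L) tup <- matrix(tup, nrow = 1L)
    cnt <- .count_tuples(tup, clusters, t)
    cnt / sum(cnt)
  })
}

.register_order_encoders <- function() {
  mats <- .order_matrices()
  .register_encoder("socnumber", .encode_socnumber,
                    defaults = list(nlag = 3L, matrices = mats))
  .register_encoder("qsorder", .encode_qsorder,
                    defaults = list(nlag = 3L, weight = 0.1,
                                    matrices = mats))
  .register_encoder("paac", .encode_paac,
                    defaults = list(lam = 3L, weight = 0.05))
  .register_encoder("apaac", .encode_apaac,
                    defaults = list(lam = 3L, weight = 0.05))
  .register_encoder("psekraac", .encode_psekraac,
                    defaults = list(subtype = "hydro", clusters = 5L,
                                    ktuple = 2L, gap = 0L))
}
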