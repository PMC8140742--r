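# Bundled physicochemical data assets. All per-residue vectors are stored in
# the canonical aminoAcids() order; literals below are written as named
# vectors and reordered programmatically so transcription order cannot drift.

.aa_order <- function(x) {
  stopifnot(setequal(names(x), aminoAcids()))
  x[aminoAcids()]
}

# Chou-style pseudo-composition scales: hydrophobicity (Tanford-derived),
# hydrophilicity (Hopp & Woods) and side-chain mass.
.scale_hydrophobicity <- .aa_order(c(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85, E = -0.74,
  G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50, M = 0.64, F = 1.19,
  P = 0.12, S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08))

.scale_hydrophilicity <- .aa_order(c(
  A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0,
  G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5,
  P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5))

.scale_sidechain_mass <- .aa_order(c(
  A = 15, R = 101, N = 58, D = 59, C = 47, Q = 72, E = 73,
  G = 1, H = 82, I = 57, L = 57, K = 73, M = 75, F = 91,
  P = 42, S = 31, T = 45, W = 130, Y = 107, V = 43))

# Grantham (1974) side-chain composition, polarity and molecular volume,
# the inputs of the Grantham distance.
.grantham_c <- .aa_order(c(
  A = 0, R = 0.65, N = 1.33, D = 1.38, C = 2.75, Q = 0.89, E = 0.92,
  G = 0.74, H = 0.58, I = 0, L = 0, K = 0.33, M = 0, F = 0,
  P = 0.39, S = 1.42, T = 0.71, W = 0.13, Y = 0.20, V = 0))

.grantham_p <- .aa_order(c(
  A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5, E = 12.3,
  G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3, M = 5.7, F = 5.2,
  P = 8.0, S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9))

.grantham_v <- .aa_order(c(
  A = 31, R = 124, N = 56, D = 54, C = 55, Q = 85, E = 83,
  G = 3, H = 96, I = 111, L = 111, K = 119, M = 105, F = 132,
  P = 32.5, S = 32, T = 61, W = 170, Y = 136, V = 84))

# Sandberg et al. (1998) five z-scales.
.zscales_raw <- list(
  A = c(0.24, -2.32, 0.60, -0.14, 1.30),
  C = c(0.84, -1.67, 3.71, 0.18, -2.65),
  D = c(3.98, 0.93, 1.93, -2.46, 0.75),
  E = c(3.11, 0.26, -0.11, -3.04, -0.25),
  F = c(-4.22, 1.94, 1.06, 0.54, -0.62),
  G = c(2.05, -4.06, 0.36, -0.82, -0.38),
  H = c(2.47, 1.95, 0.26, 3.90, 0.09),
  I = c(-3.89, -1.73, -1.71, -0.84, 0.26),
  K = c(2.29, 0.89, -2.49, 1.49, 0.31),
  L = c(-4.28, -1.30, -1.49, -0.72, 0.84),
  M = c(-2.85, -0.22, 0.47, 1.94, -0.98),
  N = c(3.05, 1.62, 1.04, -1.15, 1.61),
  P = c(-1.66, 0.27, 1.84, 0.70, 2.00),
  Q = c(1.75, 0.50, -1.44, -1.34, 0.66),
  R = c(3.52, 2.50, -3.50, 1.99, -0.17),
  S = c(2.39, -1.07, 1.15, -1.39, 0.67),
  T = c(0.75, -2.18, -1.12, -1.46, -0.40),
  V = c(-2.59, -2.64, -1.54, -0.85, -0.02),
  W = c(-4.36, 3.94, 0.59, 3.44, -1.59),
  Y = c(-2.54, 2.44, 0.43, 0.04, -1.47))

.zscale_matrix <- function() {
  m <- do.call(rbind, .zscales_raw[aminoAcids()])
  colnames(m) <- paste0("z", 1:5)
  m
}

#' Bundled amino-acid index tables
#'
#' A small curated subset of widely used 20-valued physicochemical scales
#' (AAindex-style), for the autocorrelation and per-residue encoders and for
#' the index redundancy filter. Identifiers follow the AAindex accessions of
#' the underlying scales.
#'
#' @return Named list of numeric vectors, each of length 20 in
#'   [aminoAcids()] order.
#' @export
#' @examples
#' names(aaIndexTables())
aaIndexTables <- function() {
  list(
    # Kyte & Doolittle hydropathy
    KYTJ820101 = .aa_order(c(
      A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
      G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
      P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)),
    # Hopp & Woods hydrophilicity
    HOPT810101 = .scale_hydrophilicity,
    # Grantham composition / polarity / volume
    GRAR740101 = .grantham_c,
    GRAR740102 = .grantham_p,
    GRAR740103 = .grantham_v,
    # residue molecular weight
    FASG760101 = .aa_order(c(
      A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.15, Q = 146.15,
      E = 147.13, G = 75.07, H = 155.16, I = 131.17, L = 131.17, K = 146.19,
      M = 149.21, F = 165.19, P = 115.13, S = 105.09, T = 119.12, W = 204.24,
      Y = 181.19, V = 117.15)),
    # isoelectric point
    ZIMJ680104 = .aa_order(c(
      A = 6.00, R = 10.76, N = 5.41, D = 2.77, C = 5.05, Q = 5.65, E = 3.22,
      G = 5.97, H = 7.59, I = 6.02, L = 5.98, K = 9.74, M = 5.74, F = 5.48,
      P = 6.30, S = 5.68, T = 5.66, W = 5.89, Y = 5.66, V = 5.96)))
}

# Classic Dubchak-style 3-class partitions used by the CTD descriptors;
# seven physicochemical properties, three residue groups each.
.ctd_properties <- function() {
  list(
    hydrophobicity = c("RKEDQN", "GASTPHY", "CLVIMFW"),
    vdw_volume     = c("GASTPDC", "NVEQIL", "MHKFRYW"),
    polarity       = c("LIFWCMVY", "PATGS", "HQRKNED"),
    polarizability = c("GASDT", "CPNVEQIL", "KMHFRYW"),
    charge         = c("KR", "ANCQGHILMFPSTWYV", "DE"),
    secondary_str  = c("EALMQKRH", "VIYCWFT", "GNPSD"),
    solvent_access = c("ALFCGIVW", "RKQEND", "MPSTHY"))
}

# Five physicochemical groups for the g-variant composition encoders
# (aliphatic, aromatic, positive, negative, uncharged).
.gaac_groups <- function() {
  c(aliphatic = "GAVLMI", aromatic = "FYW", positive = "KRH",
    negative = "DE", uncharged = "STCPNQ")
}

# Seven conjoint-triad classes (dipole / side-chain volume clusters).
.ctriad_classes <- function() {
  c("AGV", "ILFP", "YMTS", "HNQW", "RK", "DE", "C")
}

# Default 4-class reduction for the chaos-game encoder: nonpolar, polar
# uncharged, positively charged, negatively charged.
.fcgr_default_groups <- function() {
  c(nonpolar = "AGVLIPFMW", polar = "STCYNQ", positive = "KRH",
    negative = "DE")
}

#' Bundled reduced-alphabet family for k-tuple encodings
#'
#' A nested hierarchy of reduced amino-acid alphabets (hydrophobicity-driven
#' clustering, in the tradition of published reduced-alphabet hierarchies)
#' at sizes 2-20. Size 20 is the identity reduction. Used by the
#' reduced-alphabet k-tuple encoder.
#'
#' @param clusters Alphabet size; one of 2, 3, 4, 5, 7, 10, 20.
#' @return Character vector of residue groups; each group a string of
#'   one-letter codes, jointly partitioning the 20 amino acids.
#' @export
#' @examples
#' reducedAlphabet(5)
reducedAlphabet <- function(clusters) {
  fam <- list(
    `2`  = c("CMFILVWY", "AGTSNQDEHRKP"),
    `3`  = c("CMFILVWY", "AGTSP", "NQDEHRK"),
    `4`  = c("CMFWY", "ILV", "AGTSP", "NQDEHRK"),
    `5`  = unname(.gaac_groups()),
    `7`  = .ctriad_classes(),
    `10` = c("AG", "C", "DE", "FWY", "HNQ", "ILV", "KR", "M", "P", "ST"),
    `20` = aminoAcids())
  key <- as.character(clusters)
  if (!key %in% names(fam))
    stop(sprintf("no bundled reduced alphabet with %s clusters (have: %s)",
                 key, paste(names(fam), collapse = ", ")))
  fam[[key]]
}

# map residues -> group index under a partition given as strings of letters
.partition_map <- function(groups) {
  m <- integer(0)
  for (i in seq_along(groups)) {
    letters_i <- strsplit(groups[i], "")[[1]]
    m[letters_i] <- i
  }
  if (!setequal(names(m), aminoAcids()))
    stop("partition must cover all 20 amino acids exactly once")
  m[aminoAcids()]
}

#' Grantham physicochemical distance matrix
#'
#' The 20x20 Grantham (1974) distance, computed from side-chain composition,
#' polarity and molecular volume with the published weights and scaled so
#' the mean over all residue pairs is 100. The diagonal is zero.
#'
#' @return Numeric 20x20 matrix in [aminoAcids()] order.
#' @export
granthamDistance <- function() {
  alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399
  d <- outer(seq_len(20), seq_len(20), function(i, j) {
    sqrt(alpha * (.grantham_c[i] - .grantham_c[j])^2 +
         beta  * (.grantham_p[i] - .grantham_p[j])^2 +
         gamma * (.grantham_v[i] - .grantham_v[j])^2)
  })
  rho <- 100 / mean(d[upper.tri(d)])
  d <- d * rho
  diag(d) <- 0
  dimnames(d) <- list(aminoAcids(), aminoAcids())
  d
}

#' Constructed physicochemical distance matrix
#'
#' A synthetic Euclidean distance between residues over the three
#' standardized pseudo-composition scales (hydrophobicity, hydrophilicity,
#' side-chain mass), normalized to unit maximum. It serves as the second
#' bundled distance for the sequence-order encoders alongside
#' [granthamDistance()]; it is constructed here, not a published table.
#'
#' @return Numeric 20x20 matrix in [aminoAcids()] order.
#' @export
physchemDistance <- function() {
  s <- cbind(scale(.scale_hydrophobicity)[, 1],
             scale(.scale_hydrophilicity)[, 1],
             scale(.scale_sidechain_mass)[, 1])
  d <- as.matrix(stats::dist(s))
  d <- d / max(d)
  dimnames(d) <- list(aminoAcids(), aminoAcids())
  d
}

#' BLOSUM62 substitution matrix restricted to the 20 amino acids
#'
#' @return Numeric 20x20 matrix in [aminoAcids()] order.
#' @export
blosum62Matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62[aminoAcids(), aminoAcids()]
}
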