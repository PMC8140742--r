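# run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic two-class peptide dataset
#'
#' Fixture generator emulating a two-class biomedical peptide dataset: the
#' negative class draws residues uniformly from the 20-letter alphabet; the
#' positive class redistributes a fraction \code{biasStrength} of the
#' per-position probability mass uniformly onto \code{biasResidues}, giving
#' a composition signal of controllable strength. Sequence lengths follow a
#' log-normal model (median 26, mean about 55 residues before truncation)
#' clamped to \code{lengthRange}, mirroring the length distribution typical
#' of curated peptide collections.
#'
#' @param n Total number of records (>= 2).
#' @param imbalance Fraction of positive records in (0, 1); the positive
#'   count is \code{round(imbalance * n)}.
#' @param lengthRange Integer interval of admissible lengths, within
#'   [3, 255].
#' @param biasResidues Residues receiving extra probability mass in the
#'   positive class.
#' @param biasStrength Fraction of probability mass moved onto
#'   \code{biasResidues} for positive records, in [0, 1).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param name Dataset name.
#' @return A [PeptideSet-class] with \code{round(imbalance * n)} positive
#'   records followed by the negatives.
#' @export
#' @examples
#' d <- generateSyntheticDataset(n = 20, imbalance = 0.3, seed = 7)
#' datasetSummary(d)$n_positive
generateSyntheticDataset <- function(n, imbalance = 0.5,
                                     lengthRange = c(3L, 255L),
                                     biasResidues = c("K", "R"),
                                     biasStrength = 0.3, seed = 1L,
                                     name = "synthetic") {
  if (n < 2L) stop("invalid parameter: n must be >= 2")
  if (imbalance <= 0 || imbalance >= 1)
    stop("invalid parameter: imbalance must lie in (0, 1)")
  npos <- round(imbalance * n)
  nneg <- n - npos
  if (npos < 1L || nneg < 1L)
    stop("invalid parameter: imbalance leaves a class empty")
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2L || lengthRange[1] < 3L ||
      lengthRange[2] > 255L || lengthRange[1] > lengthRange[2])
    stop("invalid parameter: lengthRange must lie within [3, 255]")
  if (biasStrength < 0 || biasStrength >= 1)
    stop("invalid parameter: biasStrength must lie in [0, 1)")
  stopifnot(all(biasResidues %in% aminoAcids()))

  aa <- aminoAcids()
  p_neg <- rep(1 / 20, 20)
  p_pos <- (1 - biasStrength) * p_neg
  idx <- match(biasResidues, aa)
  p_pos[idx] <- p_pos[idx] + biasStrength / length(idx)

  .with_seed(seed, {
    lens <- integer(0)
    while (length(lens) < n) {
      cand <- round(stats::rlnorm(2L * n, meanlog = log(26), sdlog = 1.22))
      cand <- cand[cand >= lengthRange[1] & cand <= lengthRange[2]]
      lens <- c(lens, cand)
    }
    lens <- lens[seq_len(n)]
    draw <- function(len, p) paste(sample(aa, len, replace = TRUE, prob = p),
                                   collapse = "")
    seqs <- character(n)
    for (i in seq_len(n))
      seqs[i] <- draw(lens[i], if (i <= npos) p_pos else p_neg)
    names(seqs) <- sprintf("%s_%04d", name, seq_len(n))
    peptideSet(seqs, c(rep(1L, npos), rep(0L, nneg)), name = name)
  })
}
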