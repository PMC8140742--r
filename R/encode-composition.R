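# Composition-family encoders: k-mer compositions over the full or grouped
# alphabet, gapped pairs, sliding-window compositions, generic n-grams and
# the positional distance-frequency descriptor.
#
# All encoders here use an integer "map": a vector named by the 20 residues
# giving each residue's symbol index in the encoder's (possibly reduced)
# alphabet.

# relative overlapping k-mer frequencies over an index-mapped alphabet
.kmer_freq <- function(chars, map, n_symbols, k) {
  L <- length(chars)
  if (L < k) return(sprintf("sequence shorter than tuple size %d", k))
  idx <- unname(map[chars])
  pos <- seq_len(L - k + 1L)
  tup <- vapply(seq_len(k) - 1L, function(off) idx[pos + off],
                integer(length(pos)))
  if (length(pos) == 1L) tup <- matrix(tup, nrow = 1L)
  cnt <- .count_tuples(tup, n_symbols, k)
  cnt / sum(cnt)
}

.identity_map <- function() stats::setNames(seq_len(20L), aminoAcids())

.composition_encoder <- function(alphabet, map, k) {
  feature_names <- .kmer_names(alphabet, k)
  n_symbols <- length(alphabet)
  function(d, params, spec) {
    .encode_per_sequence(d, spec, feature_names, function(chars)
      .kmer_freq(chars, map, n_symbols, k))
  }
}

# five physicochemical groups -> integer map + one-letter group alphabet
.grouped_map <- function() {
  groups <- .gaac_groups()
  list(alphabet = names(groups), map = .partition_map(unname(groups)))
}

# -- gapped residue pairs (cksaap / cksaagp) --------------------------------

.gapped_pair_encoder <- function(alphabet, map) {
  n_symbols <- length(alphabet)
  pair_names <- .kmer_names(alphabet, 2L)
  function(d, params, spec) {
    gmax <- as.integer(params$gmax)
    if (gmax < 0L) stop("invalid parameter: gmax must be >= 0")
    feature_names <- unlist(lapply(0:gmax, function(g)
      paste0("g", g, ".", pair_names)))
    .encode_per_sequence(d, spec, feature_names, function(chars) {
      L <- length(chars)
      if (L < gmax + 2L)
        return(sprintf("sequence shorter than %d (max gap + 2)", gmax + 2L))
      idx <- unname(map[chars])
      unlist(lapply(0:gmax, function(g) {
        i <- seq_len(L - g - 1L)
        cnt <- .count_tuples(cbind(idx[i], idx[i + g + 1L]), n_symbols, 2L)
        cnt / sum(cnt)
      }))
    })
  }
}

# -- sliding-window composition (eaac / egaac) ------------------------------

# The number of windows is set by the shortest retained sequence, so the
# matrix stays rectangular on length-heterogeneous datasets; longer
# sequences contribute their leading windows only.
.sliding_encoder <- function(alphabet, map) {
  n_symbols <- length(alphabet)
  function(d, params, spec) {
    w <- as.integer(params$window)
    if (w < 1L) stop("invalid parameter: window must be >= 1")
    lens <- nchar(sequences(d))
    keep <- lens >= w
    n_windows <- if (any(keep)) min(lens[keep]) - w + 1L else 1L
    feature_names <- unlist(lapply(seq_len(n_windows), function(j)
      paste0("w", j, ".", alphabet)))
    .encode_per_sequence(d, spec, feature_names, function(chars) {
      L <- length(chars)
      if (L < w) return(sprintf("sequence shorter than window %d", w))
      idx <- unname(map[chars])
      unlist(lapply(seq_len(n_windows), function(j)
        tabulate(idx[j:(j + w - 1L)], nbins = n_symbols) / w))
    })
  }
}

# -- n-grams over an optionally reduced alphabet ----------------------------

.encode_ngram <- function(d, params, spec) {
  n <- as.integer(params$n)
  if (n < 1L) stop("invalid parameter: n must be >= 1")
  if (is.null(params$reduction)) {
    alphabet <- aminoAcids()
    map <- .identity_map()
  } else {
    groups <- params$reduction
    map <- .partition_map(unname(groups))
    alphabet <- if (is.null(names(groups)))
      paste0("c", seq_along(groups)) else names(groups)
  }
  feature_names <- .kmer_names(alphabet, n)
  .encode_per_sequence(d, spec, feature_names, function(chars)
    .kmer_freq(chars, map, length(alphabet), n))
}

# -- distance frequency -----------------------------------------------------

# For each residue, the fraction of sequence positions carrying it that fall
# in each of `bins` equal-width bins of the normalized position
# (i - 1) / (L - 1). Counts are divided by L, so the per-residue bins sum to
# that residue's single-letter composition and bins = 1 reduces to aac.
.encode_distance_frequency <- function(d, params, spec) {
  bins <- as.integer(params$bins)
  if (bins < 1L) stop("invalid parameter: bins must be >= 1")
  aa <- aminoAcids()
  feature_names <- unlist(lapply(aa, function(a)
    paste0(a, ".bin", seq_len(bins))))
  .encode_per_sequence(d, spec, feature_names, function(chars) {
    L <- length(chars)
    rel <- if (L == 1L) rep(0, 1L) else (seq_len(L) - 1L) / (L - 1L)
    bin <- pmin(floor(rel * bins) + 1L, bins)
    out <- numeric(20L * bins)
    idx <- match(chars, aa)
    for (i in seq_len(L)) {
      slot <- (idx[i] - 1L) * bins + bin[i]
      out[slot] <- out[slot] + 1
    }
    out / L
  })
}

.register_composition_encoders <- function() {
  aa <- aminoAcids()
  idmap <- .identity_map()
  g <- .grouped_map()

  .register_encoder("aac", .composition_encoder(aa, idmap, 1L))
  .register_encoder("dpc", .composition_encoder(aa, idmap, 2L))
  .register_encoder("tpc", .composition_encoder(aa, idmap, 3L))
  .register_encoder("gaac", .composition_encoder(g$alphabet, g$map, 1L))
  .register_encoder("gdpc", .composition_encoder(g$alphabet, g$map, 2L))
  .register_encoder("gtpc", .composition_encoder(g$alphabet, g$map, 3L))
  .register_encoder("cksaap", .gapped_pair_encoder(aa, idmap),
                    defaults = list(gmax = 2L))
  .register_encoder("cksaagp", .gapped_pair_encoder(g$alphabet, g$map),
                    defaults = list(gmax = 2L))
  .register_encoder("eaac", .sliding_encoder(aa, idmap),
                    defaults = list(window = 5L))
  .register_encoder("egaac", .sliding_encoder(g$alphabet, g$map),
                    defaults = list(window = 5L))
  .register_encoder("ngram", .encode_ngram,
                    defaults = list(n = 2L, reduction = NULL))
  .register_encoder("distance_frequency", .encode_distance_frequency,
                    defaults = list(bins = 5L))
}
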