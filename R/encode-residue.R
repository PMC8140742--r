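# Per-residue (position-wise) encoders requiring equal-length (pre-aligned)
# input, and the chaos-game representation encoder.

# per-position block encoders share this wrapper: `block` maps one residue
# to a numeric vector; gaps encode as zero blocks
.per_residue_encoder <- function(block_names, block) {
  function(d, params, spec) {
    lens <- nchar(sequences(d))
    if (length(unique(lens)) != 1L)
      stop(paste("alignment required: per-residue encodings need",
                 "equal-length sequences (align the input first)"))
    L <- lens[1]
    feature_names <- unlist(lapply(seq_len(L), function(p)
      paste0("p", p, ".", block_names)))
    width <- length(block_names)
    .encode_per_sequence(d, spec, feature_names, function(chars) {
      out <- numeric(L * width)
      for (p in seq_len(L)) {
        if (chars[p] != "-")
          out[((p - 1L) * width + 1L):(p * width)] <- block(chars[p])
      }
      out
    }, allow_gaps = TRUE)
  }
}

.encode_binary <- function(d, params, spec) {
  aa <- aminoAcids()
  enc <- .per_residue_encoder(aa, function(a) as.numeric(aa == a))
  enc(d, params, spec)
}

.encode_blosum62 <- function(d, params, spec) {
  B <- blosum62Matrix()
  enc <- .per_residue_encoder(colnames(B), function(a) B[a, ])
  enc(d, params, spec)
}

.encode_zscale <- function(d, params, spec) {
  Z <- .zscale_matrix()
  enc <- .per_residue_encoder(colnames(Z), function(a) Z[a, ])
  enc(d, params, spec)
}

.encode_aaindex <- function(d, params, spec) {
  idx <- .resolve_indices(params$index)
  id <- names(idx)[1]
  v <- idx[[1]]
  enc <- .per_residue_encoder(id, function(a) unname(v[a]))
  enc(d, params, spec)
}

# chaos-game representation: the sequence is reduced to 4 symbols mapped to
# the unit-square corners; the iterated midpoint orbit is histogrammed on a
# resolution x resolution grid and normalized to sum 1
.encode_fcgr <- function(d, params, spec) {
  res <- as.integer(params$resolution)
  if (res < 1L || bitwAnd(res, res - 1L) != 0L)
    stop("invalid parameter: resolution must be a power of two")
  groups <- params$reduction
  map <- .partition_map(unname(groups))
  if (length(unique(map)) != 4L)
    stop("invalid parameter: reduction must have exactly 4 classes")
  corners <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
  feature_names <- unlist(lapply(seq_len(res), function(r)
    paste0("r", r, ".c", seq_len(res))))
  .encode_per_sequence(d, spec, feature_names, function(chars) {
    idx <- unname(map[chars])
    x <- 0.5; y <- 0.5
    grid <- matrix(0, nrow = res, ncol = res)
    for (s in idx) {
      x <- (x + corners[s, 1]) / 2
      y <- (y + corners[s, 2]) / 2
      cx <- min(floor(x * res) + 1L, res)
      cy <- min(floor(y * res) + 1L, res)
      grid[cy, cx] <- grid[cy, cx] + 1
    }
    as.vector(t(grid)) / length(idx)
  })
}

.register_residue_encoders <- function() {
  .register_encoder("binary", .encode_binary)
  .register_encoder("blosum62", .encode_blosum62)
  .register_encoder("zscale", .encode_zscale)
  .register_encoder("aaindex", .encode_aaindex,
                    defaults = list(index = "KYTJ820101"))
  .register_encoder("fcgr", .encode_fcgr,
                    defaults = list(resolution = 8L,
                                    reduction = .fcgr_default_groups()))
}
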