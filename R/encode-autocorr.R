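# Autocorrelation descriptors: Moran, Geary and normalized Moreau-Broto
# statistics of standardized amino-acid index profiles at lags 1..lag.

# z-standardize a 20-value index; zero variance is an error
.standardize_index <- function(values, id = "index") {
  if (length(values) != 20L)
    stop(sprintf("invalid index '%s': needs exactly 20 values", id))
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop(sprintf("invalid index '%s': zero variance", id))
  (values - mean(values)) / s
}

# resolve the `indices` parameter: named list of 20-vectors, or character
# ids into aaIndexTables()
.resolve_indices <- function(indices) {
  if (is.character(indices)) {
    tabs <- aaIndexTables()
    missing <- setdiff(indices, names(tabs))
    if (length(missing) > 0L)
      stop(sprintf("unknown amino-acid index id(s): %s",
                   paste(missing, collapse = ", ")))
    indices <- tabs[indices]
  }
  if (is.null(names(indices)))
    names(indices) <- paste0("idx", seq_along(indices))
  lapply(stats::setNames(names(indices), names(indices)), function(id) {
    v <- .standardize_index(unname(indices[[id]]), id)
    stats::setNames(v, aminoAcids())
  })
}

# the three classic statistics on a per-position profile P at lag d;
# sequences of a single repeated residue have zero profile variance, for
# which Moran and Geary are undefined and reported as 0
.autocorr_value <- function(P, dlag, variant) {
  L <- length(P)
  i <- seq_len(L - dlag)
  switch(variant,
    moran = {
      Pbar <- mean(P)
      den <- sum((P - Pbar)^2) / L
      if (den == 0) 0
      else (sum((P[i] - Pbar) * (P[i + dlag] - Pbar)) / (L - dlag)) / den
    },
    geary = {
      Pbar <- mean(P)
      den <- sum((P - Pbar)^2) / (L - 1L)
      if (den == 0) 0
      else (sum((P[i] - P[i + dlag])^2) / (2 * (L - dlag))) / den
    },
    nmbroto = sum(P[i] * P[i + dlag]) / (L - dlag))
}

.autocorr_encoder <- function(variant) {
  function(d, params, spec) {
    lag <- as.integer(params$lag)
    if (lag < 1L) stop("invalid parameter: lag must be >= 1")
    idx <- .resolve_indices(params$indices)
    feature_names <- unlist(lapply(names(idx), function(id)
      paste0(id, ".lag", seq_len(lag))))
    .encode_per_sequence(d, spec, feature_names, function(chars) {
      L <- length(chars)
      if (L <= lag)
        return(sprintf("sequence length %d <= lag %d", L, lag))
      unlist(lapply(idx, function(v) {
        P <- unname(v[chars])
        vapply(seq_len(lag), function(dl) .autocorr_value(P, dl, variant),
               numeric(1))
      }))
    })
  }
}

.register_autocorr_encoders <- function() {
  defaults <- list(lag = 4L, indices = c("KYTJ820101", "HOPT810101"))
  .register_encoder("moran", .autocorr_encoder("moran"), defaults)
  .register_encoder("geary", .autocorr_encoder("geary"), defaults)
  .register_encoder("nmbroto", .autocorr_encoder("nmbroto"), defaults)
}
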