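# CTD (composition / transition / distribution over 3-class physicochemical
# partitions) and the conjoint-triad family over the 7-class reduced
# alphabet.

# per-property integer class maps (residue -> class 1..3)
.ctd_maps <- function(properties = .ctd_properties()) {
  lapply(properties, .partition_map)
}

.encode_ctdc <- function(d, params, spec) {
  maps <- .ctd_maps(params$properties)
  feature_names <- unlist(lapply(names(maps), function(p)
    paste0(p, ".g", 1:3)))
  .encode_per_sequence(d, spec, feature_names, function(chars) {
    unlist(lapply(maps, function(m)
      tabulate(unname(m[chars]), nbins = 3L) / length(chars)))
  })
}

# transitions: fraction of adjacent residue pairs whose classes differ,
# split by unordered class pair (1-2, 1-3, 2-3), normalized by L - 1
.encode_ctdt <- function(d, params, spec) {
  maps <- .ctd_maps(params$properties)
  feature_names <- unlist(lapply(names(maps), function(p)
    paste0(p, c(".t12", ".t13", ".t23"))))
  .encode_per_sequence(d, spec, feature_names, function(chars) {
    L <- length(chars)
    if (L < 2L) return("sequence shorter than 2 (no adjacent pairs)")
    unlist(lapply(maps, function(m) {
      cls <- unname(m[chars])
      a <- cls[-L]; b <- cls[-1L]
      lo <- pmin(a, b); hi <- pmax(a, b)
      c(sum(lo == 1L & hi == 2L), sum(lo == 1L & hi == 3L),
        sum(lo == 2L & hi == 3L)) / (L - 1L)
    }))
  })
}

# distribution: for each class, the sequence-relative position (percent) of
# its first, 25%, 50%, 75% and last occurrence; absent class -> zeros
.encode_ctdd <- function(d, params, spec) {
  maps <- .ctd_maps(params$properties)
  landmarks <- c("first", "p25", "p50", "p75", "p100")
  feature_names <- unlist(lapply(names(maps), function(p)
    unlist(lapply(1:3, function(g) paste0(p, ".g", g, ".", landmarks)))))
  .encode_per_sequence(d, spec, feature_names, function(chars) {
    L <- length(chars)
    unlist(lapply(maps, function(m) {
      cls <- unname(m[chars])
      unlist(lapply(1:3, function(g) {
        pos <- which(cls == g)
        if (length(pos) == 0L) return(numeric(5L))
        N <- length(pos)
        ranks <- pmax(1L, c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * N)))
        pos[ranks] / L * 100
      }))
    }))
  })
}

# conjoint triads: residues mapped to 7 classes; triads (i, i+k+1, i+2k+2)
# counted per skip k and min-max normalized within each 343-feature block
.encode_conjoint_triad <- function(d, params, spec) {
  kmax <- as.integer(params$kmax)
  if (kmax < 0L) stop("invalid parameter: kmax must be >= 0")
  classes <- .ctriad_classes()
  map <- .partition_map(classes)
  tri_names <- .kmer_names(paste0("c", 1:7), 3L, sep = ".")
  feature_names <- unlist(lapply(0:kmax, function(k)
    paste0("k", k, ".", tri_names)))
  .encode_per_sequence(d, spec, feature_names, function(chars) {
    L <- length(chars)
    if (L < 2L * kmax + 3L)
      return(sprintf("sequence shorter than %d (2k+3 for k = %d)",
                     2L * kmax + 3L, kmax))
    idx <- unname(map[chars])
    unlist(lapply(0:kmax, function(k) {
      i <- seq_len(L - 2L * (k + 1L))
      cnt <- .count_tuples(cbind(idx[i], idx[i + k + 1L],
                                 idx[i + 2L * (k + 1L)]), 7L, 3L)
      rng <- range(cnt)
      if (rng[2] > rng[1]) (cnt - rng[1]) / (rng[2] - rng[1])
      else numeric(length(cnt))
    }))
  })
}

.register_physchem_encoders <- function() {
  props <- .ctd_properties()
  .register_encoder("ctdc", .encode_ctdc,
                    defaults = list(properties = props))
  .register_encoder("ctdt", .encode_ctdt,
                    defaults = list(properties = props))
  .register_encoder("ctdd", .encode_ctdd,
                    defaults = list(properties = props))
  .register_encoder("ctriad", function(d, params, spec)
    .encode_conjoint_triad(d, list(kmax = 0L), spec), defaults = list())
  .register_encoder("ksctriad", .encode_conjoint_triad,
                    defaults = list(kmax = 1L))
}
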