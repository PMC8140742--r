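# Parameter-grid expansion and redundancy filtering of encoding specs.

#' Expand parameter grids into encoding specs
#'
#' Builds the union over encoder groups of the Cartesian products of each
#' group's parameter axes, so the spec count is the product-sum of the axis
#' sizes. Duplicated axis values are removed before the product; duplicated
#' value combinations are removed after it.
#'
#' @param grids List of grids; each grid is a list with elements
#'   \code{group} (registry name) and \code{axes} (named list of finite
#'   value vectors; may be empty for parameterless encoders).
#' @return List of [EncodingSpec-class], in grid order with the last axis
#'   varying fastest.
#' @export
#' @examples
#' specs <- expandEncodingGrid(list(
#'   list(group = "cksaap", axes = list(gmax = c(0, 1, 2))),
#'   list(group = "aac", axes = list())))
#' length(specs)
expandEncodingGrid <- function(grids) {
  out <- list()
  for (grid in grids) {
    if (!exists(grid$group, envir = .registry))
      stop(sprintf("unknown encoder group '%s' (registry error)",
                   grid$group))
    axes <- grid$axes
    if (is.null(axes) || length(axes) == 0L) {
      out <- c(out, list(encodingSpec(grid$group)))
      next
    }
    axes <- lapply(axes, unique)
    combos <- do.call(expand.grid, c(rev(axes),
                                     list(KEEP.OUT.ATTRS = FALSE,
                                          stringsAsFactors = FALSE)))
    combos <- combos[, rev(seq_along(axes)), drop = FALSE]
    specs <- lapply(seq_len(nrow(combos)), function(i) {
      p <- as.list(combos[i, , drop = FALSE])
      names(p) <- names(axes)
      new("EncodingSpec", group = grid$group, params = p)
    })
    out <- c(out, specs)
  }
  ids <- vapply(out, specId, character(1))
  out[!duplicated(ids)]
}

#' Filter redundant amino-acid index tables
#'
#' Greedy clustering of 20-valued index tables on absolute Pearson
#' correlation: indices are visited in input order; an index joins the
#' first cluster whose seed it correlates with at \code{|r| >= threshold},
#' otherwise it seeds a new cluster. Each cluster is represented by its
#' highest-variance member (ties broken by lexicographic id).
#'
#' @param indices Named list of 20-value numeric vectors.
#' @param threshold Absolute-correlation cut in (0, 1].
#' @return Named list of surviving index tables, in original input order.
#' @export
filterIndexTables <- function(indices, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1)
    stop("invalid parameter: threshold must lie in (0, 1]")
  if (length(indices) == 0L) stop("at least one index required")
  ids <- names(indices)
  if (is.null(ids)) stop("indices must be named")
  vals <- lapply(indices, function(v) .standardize_index(unname(v)))
  seeds <- integer(0)          # index of each cluster's seed
  members <- list()            # member positions per cluster
  for (i in seq_along(vals)) {
    placed <- FALSE
    for (cl in seq_along(seeds)) {
      r <- abs(stats::cor(vals[[i]], vals[[seeds[cl]]]))
      if (r >= threshold) {
        members[[cl]] <- c(members[[cl]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, i)
      members[[length(seeds)]] <- i
    }
  }
  reps <- vapply(members, function(m) {
    v <- vapply(m, function(i) stats::var(unname(indices[[i]])), numeric(1))
    best <- m[v == max(v)]
    best[order(ids[best])][1]
  }, integer(1))
  indices[sort(reps)]
}

#' Filter redundant encoding specs by probing correlation
#'
#' Encodes a probe dataset under every spec and greedily removes any spec
#' whose encoded matrix has an adjusted RV-coefficient at or above
#' \code{threshold} with an already-retained spec (first-kept strategy, in
#' input order). Specs that fail to encode the probe are logged and
#' excluded rather than fatal.
#'
#' @param specs List of [EncodingSpec-class].
#' @param probe A [PeptideSet-class] used to measure encoding redundancy.
#' @param threshold Adjusted RV-coefficient cut; redundant at or above.
#' @return The retained specs, in input order.
#' @export
filterSpecsByProbe <- function(specs, probe, threshold = 0.95) {
  kept <- list()
  kept_mats <- list()
  for (spec in specs) {
    enc <- tryCatch(encodeDataset(probe, spec), error = function(e) e)
    if (inherits(enc, "error")) {
      message(sprintf("excluding %s: %s", specId(spec),
                      conditionMessage(enc)))
      next
    }
    M <- featureMatrix(enc)
    redundant <- FALSE
    for (K in kept_mats) {
      shared <- intersect(rownames(M), rownames(K))
      if (length(shared) < 3L) next
      rv <- rvAdjusted(M[shared, , drop = FALSE], K[shared, , drop = FALSE])
      if (!is.na(rv) && rv >= threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) {
      kept <- c(kept, list(spec))
      kept_mats <- c(kept_mats, list(M))
    }
  }
  kept
}
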