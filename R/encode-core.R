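#' Create an encoding spec
#'
#' @param group Encoder group name; must exist in the registry (see
#'   [encodingGroups()]).
#' @param ... Named parameter values for the group.
#' @return An [EncodingSpec-class].
#' @export
#' @examples
#' encodingSpec("cksaap", gmax = 2)
encodingSpec <- function(group, ...) {
  new("EncodingSpec", group = group, params = list(...))
}

#' Canonical string id of an encoding spec
#'
#' @param spec An [EncodingSpec-class].
#' @return A string like \code{"cksaap(gmax=2)"}; parameters appear in
#'   sorted name order so equal specs share one id.
#' @export
specId <- function(spec) {
  p <- spec@params
  if (length(p) == 0L) return(spec@group)
  p <- p[order(names(p))]
  vals <- vapply(p, function(v) paste(format(v, trim = TRUE), collapse = "+"),
                 character(1))
  sprintf("%s(%s)", spec@group, paste(names(p), vals, sep = "=",
                                      collapse = ","))
}

# registry of encoder groups: name -> list(fn, defaults)
.registry <- new.env(parent = emptyenv())

.register_encoder <- function(group, fn, defaults = list()) {
  assign(group, list(fn = fn, defaults = defaults), envir = .registry)
}

#' List registered encoder groups
#'
#' @return Character vector of group names known to the registry.
#' @export
encodingGroups <- function() sort(ls(.registry))

#' Encode a peptide dataset under a spec
#'
#' Dispatches to the registered encoder for \code{spec@group}, with the
#' group's default parameters filled in for any not given. Row order of the
#' result follows the input record order; records the spec cannot encode
#' (e.g. sequences too short) are dropped and listed in
#' [droppedRecords()].
#'
#' @param d A [PeptideSet-class].
#' @param spec An [EncodingSpec-class] or a group name (encoded with
#'   defaults).
#' @return An [EncodedSet-class].
#' @export
#' @examples
#' d <- peptideSet(c(a = "ACDK", b = "KKRR"), c(0, 1))
#' encodeDataset(d, "aac")
encodeDataset <- function(d, spec) {
  if (is.character(spec)) spec <- encodingSpec(spec)
  if (!exists(spec@group, envir = .registry))
    stop(sprintf("unknown encoder group '%s' (registry error)", spec@group))
  entry <- get(spec@group, envir = .registry)
  params <- utils::modifyList(entry$defaults, spec@params)
  unknown <- setdiff(names(spec@params), names(entry$defaults))
  if (length(unknown) > 0L)
    stop(sprintf("unknown parameter(s) for group '%s': %s", spec@group,
                 paste(unknown, collapse = ", ")))
  full <- new("EncodingSpec", group = spec@group, params = params)
  entry$fn(d, params, full)
}

# Shared harness: apply fn(sequence_character_vector) per record. fn returns
# a numeric feature vector, or a character scalar naming a drop reason.
# Gap characters (aligned input) are only meaningful to the per-residue
# encoders; everywhere else a gapped record is dropped with a reason.
.encode_per_sequence <- function(d, spec, feature_names, fn,
                                 allow_gaps = FALSE) {
  ids <- recordIds(d)
  seqs <- sequences(d)
  rows <- vector("list", length(ids))
  dropped_id <- character(0)
  dropped_reason <- character(0)
  for (i in seq_along(ids)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    out <- if (!allow_gaps && any(chars == "-"))
      "contains gap characters" else fn(chars)
    if (is.character(out)) {
      dropped_id <- c(dropped_id, ids[i])
      dropped_reason <- c(dropped_reason, out)
      rows[[i]] <- NULL
    } else {
      stopifnot(length(out) == length(feature_names))
      rows[[i]] <- out
    }
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep))
    stop(sprintf("empty encoding: all %d record(s) dropped under %s",
                 length(ids), specId(spec)))
  mat <- do.call(rbind, rows[keep])
  dimnames(mat) <- list(ids[keep], feature_names)
  new("EncodedSet", spec = spec, mat = mat,
      dropped = data.frame(id = dropped_id, reason = dropped_reason,
                           stringsAsFactors = FALSE))
}

# all k-tuples over an alphabet, first slot varying slowest, matching the
# integer coding of .count_tuples
.kmer_names <- function(alphabet, k, sep = NULL) {
  if (is.null(sep)) sep <- if (any(nchar(alphabet) > 1L)) "." else ""
  if (k == 1L) return(alphabet)
  g <- do.call(expand.grid, c(rep(list(alphabet), k),
                              list(KEEP.OUT.ATTRS = FALSE,
                                   stringsAsFactors = FALSE)))
  apply(g[, k:1, drop = FALSE], 1L, paste, collapse = sep)
}

# count tuples given as a matrix of symbol indices (columns = tuple slots)
.count_tuples <- function(idx_matrix, n_symbols, k) {
  if (nrow(idx_matrix) == 0L) return(numeric(n_symbols^k))
  code <- rep(0L, nrow(idx_matrix))
  for (j in seq_len(k)) code <- code * n_symbols + (idx_matrix[, j] - 1L)
  tabulate(code + 1L, nbins = n_symbols^k)
}

#' Serialize an encoded dataset to CSV with a JSON sidecar
#'
#' Writes the feature matrix as CSV (first column \code{row_id}) plus a
#' \code{<path>.json} sidecar holding the spec and drop bookkeeping.
#'
#' @param e An [EncodedSet-class].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeEncodedSet <- function(e, path) {
  df <- data.frame(row_id = rownames(e@mat), e@mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(group = e@spec@group, params = e@spec@params,
               dropped = e@dropped)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an encoded dataset written by [writeEncodedSet()]
#'
#' @param path CSV path written by [writeEncodedSet()].
#' @return An [EncodedSet-class].
#' @export
readEncodedSet <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$row_id
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dropped <- if (length(side$dropped) == 0L)
    data.frame(id = character(0), reason = character(0))
  else as.data.frame(side$dropped, stringsAsFactors = FALSE)
  new("EncodedSet",
      spec = new("EncodingSpec", group = side$group,
                 params = as.list(side$params)),
      mat = mat, dropped = dropped)
}
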