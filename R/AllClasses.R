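#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

#' The 20-letter amino-acid alphabet
#'
#' Canonical ordering used for all composition-type feature names.
#'
#' @return Character vector of the 20 natural amino acids (one-letter codes).
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' PeptideSet: a labelled two-class peptide dataset
#'
#' An S4 container for a named set of amino-acid sequences with binary class
#' labels, the unit of input for all encoders and the benchmark harness.
#' Sequences are held as a [Biostrings::AAStringSet]; record ids are the
#' element names and must be unique.
#'
#' @slot name Dataset name.
#' @slot seqs An \code{AAStringSet}; names are record ids.
#' @slot labels Integer vector of class labels in \{0, 1\}, parallel to
#'   \code{seqs}.
#'
#' @export
setClass("PeptideSet",
  slots = c(name = "character", seqs = "AAStringSet", labels = "integer"))

setValidity("PeptideSet", function(object) {
  ids <- names(object@seqs)
  if (length(object@seqs) == 0L)
    return("PeptideSet must contain at least one record")
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("all records must have non-empty ids")
  if (anyDuplicated(ids))
    return(sprintf("duplicate record ids: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@labels) != length(object@seqs))
    return("labels must be parallel to sequences")
  if (!all(object@labels %in% c(0L, 1L)))
    return("labels must be binary (0/1)")
  seqs <- as.character(object@seqs)
  if (any(nchar(seqs) < 1L))
    return("sequences must have length >= 1")
  # '-' is admitted so pre-aligned input can be represented; only the
  # per-residue encoders interpret it
  bad <- grepl(sprintf("[^%s-]", paste(aminoAcids(), collapse = "")), seqs)
  if (any(bad))
    return(sprintf("non-standard amino-acid characters in record(s): %s",
                   paste(utils::head(ids[bad], 5L), collapse = ", ")))
  TRUE
})

#' EncodingSpec: one fully parameterized encoding instance
#'
#' Identifies an encoder group from the registry together with a complete
#' parameter assignment, i.e. one point of a parameter grid.
#'
#' @slot group Registry name of the encoder (e.g. \code{"aac"},
#'   \code{"cksaap"}).
#' @slot params Named list of parameter values; may be empty for
#'   parameterless encoders.
#'
#' @export
setClass("EncodingSpec", slots = c(group = "character", params = "list"))

setValidity("EncodingSpec", function(object) {
  if (length(object@group) != 1L || is.na(object@group) || object@group == "")
    return("group must be a single non-empty string")
  if (length(object@params) > 0L &&
      (is.null(names(object@params)) || any(names(object@params) == "")))
    return("all params must be named")
  TRUE
})

#' EncodedSet: the numeric feature matrix produced by one encoding
#'
#' Holds the feature matrix (one row per retained record, in input order),
#' the spec that produced it, and bookkeeping for records that were dropped
#' (e.g. sequences too short for the spec).
#'
#' @slot spec The [EncodingSpec-class] that produced the matrix.
#' @slot mat Numeric matrix; rownames are record ids, colnames are feature
#'   names.
#' @slot dropped \code{data.frame} with columns \code{id} and \code{reason}
#'   for records excluded from \code{mat}.
#'
#' @export
setClass("EncodedSet",
  slots = c(spec = "EncodingSpec", mat = "matrix", dropped = "data.frame"))

setValidity("EncodedSet", function(object) {
  if (!is.numeric(object@mat))
    return("feature matrix must be numeric")
  if (nrow(object@mat) > 0L && is.null(rownames(object@mat)))
    return("feature matrix must carry record ids as rownames")
  if (anyNA(object@mat))
    return("feature matrix must not contain missing values")
  if (!all(c("id", "reason") %in% colnames(object@dropped)))
    return("dropped table needs columns id, reason")
  TRUE
})

#' CVResult: per-fold outputs of a repeated stratified cross-validation
#'
#' One row per (repetition, fold); each row stores the held-out record ids
#' and three parallel vectors: true classes, predicted probabilities of the
#' positive class, and thresholded predicted classes. With the defaults of
#' 5 folds and 10 repetitions the result holds 50 rows.
#'
#' @slot spec The [EncodingSpec-class] of the encoded dataset that was
#'   cross-validated.
#' @slot folds List of fold records, each a list with elements
#'   \code{repetition}, \code{fold}, \code{ids}, \code{truth}, \code{prob},
#'   \code{pred}.
#'
#' @export
setClass("CVResult", slots = c(spec = "EncodingSpec", folds = "list"))

setValidity("CVResult", function(object) {
  for (f in object@folds) {
    need <- c("repetition", "fold", "ids", "truth", "prob", "pred")
    if (!all(need %in% names(f)))
      return("each fold record needs repetition, fold, ids, truth, prob, pred")
    n <- length(f$ids)
    if (length(f$truth) != n || length(f$prob) != n || length(f$pred) != n)
      return("fold vectors must share one length")
    if (any(f$prob < 0 | f$prob > 1))
      return("probabilities must lie in [0, 1]")
  }
  TRUE
})

#' ClippedStructure: residue coordinates clipped from a template structure
#'
#' The result of the tertiary-structure approximation for one query peptide:
#' all atoms of the residues of the best database hit that align to the
#' query, together with the hit's provenance.
#'
#' @slot queryId Query record id.
#' @slot dbEntry Identifier of the database chain the clip was taken from
#'   (\code{"<entry>_<chain>"}).
#' @slot evalue E-value of the selected hit.
#' @slot sequence One-letter sequence of the clipped residues; equals the
#'   matched query subsequence.
#' @slot queryRange Integer length-2 vector, 1-based inclusive query
#'   interval.
#' @slot dbRange Integer length-2 vector, 1-based inclusive residue interval
#'   in the database chain.
#' @slot atoms \code{data.frame} of atom records (columns \code{elety},
#'   \code{resid}, \code{resno}, \code{x}, \code{y}, \code{z}).
#'
#' @export
setClass("ClippedStructure",
  slots = c(queryId = "character", dbEntry = "character", evalue = "numeric",
            sequence = "character", queryRange = "integer",
            dbRange = "integer", atoms = "data.frame"))

setValidity("ClippedStructure", function(object) {
  if (diff(object@queryRange) != diff(object@dbRange))
    return("query and db ranges must have equal length")
  if (nchar(object@sequence) != object@queryRange[2] - object@queryRange[1] + 1L)
    return("clip sequence length must match the matched range")
  if (!all(is.finite(unlist(object@atoms[, c("x", "y", "z")]))))
    return("atom coordinates must be finite")
  TRUE
})

setMethod("show", "PeptideSet", function(object) {
  lab <- object@labels
  cat(sprintf("PeptideSet '%s': %d records (%d positive / %d negative)\n",
              object@name, length(lab), sum(lab == 1L), sum(lab == 0L)))
  w <- Biostrings::width(object@seqs)
  cat(sprintf("  length range %d-%d, mean %.2f\n", min(w), max(w), mean(w)))
})

setMethod("show", "EncodingSpec", function(object) {
  cat(specId(object), "\n")
})

setMethod("show", "EncodedSet", function(object) {
  cat(sprintf("EncodedSet [%s]: %d x %d features, %d record(s) dropped\n",
              specId(object@spec), nrow(object@mat), ncol(object@mat),
              nrow(object@dropped)))
})

setMethod("show", "CVResult", function(object) {
  reps <- vapply(object@folds, `[[`, numeric(1), "repetition")
  cat(sprintf("CVResult [%s]: %d fold rows (%d repetition(s))\n",
              specId(object@spec), length(object@folds),
              length(unique(reps))))
})

setMethod("show", "ClippedStructure", function(object) {
  cat(sprintf("ClippedStructure %s <- %s (e-value %.3g): %s [%d-%d]\n",
              object@queryId, object@dbEntry, object@evalue,
              object@sequence, object@dbRange[1], object@dbRange[2]))
})
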