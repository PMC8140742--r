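#' Accessors for pepBench classes
#'
#' Small accessor functions used instead of direct slot access.
#'
#' @param x A pepBench S4 object.
#' @return \code{datasetName}: the dataset name; \code{sequences}: named
#'   character vector of sequences; \code{classLabels}: named integer label
#'   vector; \code{recordIds}: character vector of record ids;
#'   \code{featureMatrix}: the numeric feature matrix; \code{droppedRecords}:
#'   the drop-bookkeeping \code{data.frame}; \code{encodingSpecOf}: the
#'   [EncodingSpec-class]; \code{foldRecords}: list of per-fold records.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("droppedRecords", function(x) standardGeneric("droppedRecords"))
#' @rdname accessors
#' @export
setGeneric("encodingSpecOf", function(x) standardGeneric("encodingSpecOf"))
#' @rdname accessors
#' @export
setGeneric("foldRecords", function(x) standardGeneric("foldRecords"))

#' @rdname accessors
setMethod("datasetName", "PeptideSet", function(x) x@name)

#' @rdname accessors
setMethod("sequences", "PeptideSet", function(x) {
  s <- as.character(x@seqs)
  names(s) <- names(x@seqs)
  s
})

#' @rdname accessors
setMethod("classLabels", "PeptideSet", function(x) {
  stats::setNames(x@labels, names(x@seqs))
})

#' @rdname accessors
setMethod("recordIds", "PeptideSet", function(x) names(x@seqs))

#' @rdname accessors
setMethod("recordIds", "EncodedSet", function(x) rownames(x@mat))

#' @rdname accessors
setMethod("featureMatrix", "EncodedSet", function(x) x@mat)

#' @rdname accessors
setMethod("droppedRecords", "EncodedSet", function(x) x@dropped)

#' @rdname accessors
setMethod("encodingSpecOf", "EncodedSet", function(x) x@spec)

#' @rdname accessors
setMethod("encodingSpecOf", "CVResult", function(x) x@spec)

#' @rdname accessors
setMethod("foldRecords", "CVResult", function(x) x@folds)

#' Subset a PeptideSet by record id or position
#'
#' @param x A [PeptideSet-class].
#' @param i Character ids or integer/logical positions.
#' @param j,...,drop Ignored.
#' @return A [PeptideSet-class] with the selected records, in the order of
#'   \code{i}.
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  if (anyNA(i)) stop("unknown record id(s)")
  new("PeptideSet", name = x@name, seqs = x@seqs[i], labels = x@labels[i])
})

#' @describeIn accessors Number of records in a PeptideSet.
#' @export
setMethod("length", "PeptideSet", function(x) length(x@seqs))
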