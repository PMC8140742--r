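#' Construct a PeptideSet from sequences and labels
#'
#' Applies sanitization before validation: sequences are uppercased and, in
#' lenient mode, records containing characters outside the 20-letter
#' amino-acid alphabet (B, J, O, U, X, Z, gaps, ...) are dropped with a
#' message. In strict mode (default) such records raise an error naming the
#' offending record.
#'
#' @param sequences Named character vector of amino-acid sequences (names
#'   are record ids).
#' @param labels Integer/numeric vector of 0/1 class labels, parallel to
#'   \code{sequences}.
#' @param name Dataset name.
#' @param strict If \code{TRUE}, reject records with non-standard residues;
#'   if \code{FALSE}, drop them with a message.
#' @param aligned If \code{TRUE}, accept the gap character \code{-}
#'   (pre-aligned input for the per-residue encoders).
#' @return A [PeptideSet-class].
#' @export
#' @examples
#' peptideSet(c(p1 = "ACDE", p2 = "KLMN"), c(1, 0))
peptideSet <- function(sequences, labels, name = "dataset", strict = TRUE,
                       aligned = FALSE) {
  if (length(sequences) == 0L) stop("empty input: no sequences")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (length(labels) != length(sequences))
    stop("labels must be parallel to sequences")
  sequences <- toupper(sequences)
  allowed <- paste(aminoAcids(), collapse = "")
  if (aligned) allowed <- paste0(allowed, "-")
  ok <- !grepl(sprintf("[^%s]", allowed), sequences)
  if (!all(ok)) {
    bad <- names(sequences)[!ok]
    badchar <- unique(unlist(strsplit(
      gsub(sprintf("[%s]", paste(aminoAcids(), collapse = "")), "",
           sequences[!ok]), "")))
    if (strict)
      stop(sprintf(
        "record(s) %s contain non-standard residue(s) %s (strict mode)",
        paste(utils::head(bad, 5L), collapse = ", "),
        paste(badchar, collapse = ", ")))
    message(sprintf("dropping %d record(s) with non-standard residues: %s",
                    sum(!ok), paste(utils::head(bad, 5L), collapse = ", ")))
    sequences <- sequences[ok]
    labels <- labels[ok]
    if (length(sequences) == 0L) stop("all records dropped by sanitization")
  }
  dup <- duplicated(sequences)
  if (any(dup))
    message(sprintf("%d duplicated sequence(s) present (kept, flagged)",
                    sum(dup)))
  new("PeptideSet", name = name,
      seqs = Biostrings::AAStringSet(sequences),
      labels = as.integer(labels))
}

#' Read a labelled peptide dataset from FASTA
#'
#' Labels come from the FASTA header convention \code{>id|label}; a sidecar
#' CSV (columns \code{id,label}) overrides header labels where given.
#'
#' @param path FASTA file path.
#' @param labels Optional path of a CSV label table with columns
#'   \code{id,label}.
#' @param name Dataset name; defaults to the file base name.
#' @param strict,aligned Passed to [peptideSet()].
#' @return A [PeptideSet-class]; record order follows the file.
#' @export
readFastaDataset <- function(path, labels = NULL, name = NULL,
                             strict = TRUE, aligned = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) stop(sprintf("empty input file: %s", path))
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop(sprintf("empty input file: %s", path))
  headers <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  labs <- rep(NA_integer_, length(ids))
  has_lab <- lengths(parts) >= 2L
  labs[has_lab] <- as.integer(vapply(parts[has_lab], `[[`, character(1), 2L))
  if (!is.null(labels)) {
    tab <- utils::read.csv(labels, stringsAsFactors = FALSE)
    if (!all(c("id", "label") %in% colnames(tab)))
      stop("label table must have columns id,label")
    m <- match(ids, tab$id)
    labs[!is.na(m)] <- as.integer(tab$label[m[!is.na(m)]])
  }
  if (anyNA(labs))
    stop(sprintf("unlabeled record(s): %s",
                 paste(utils::head(ids[is.na(labs)], 5L), collapse = ", ")))
  seqs <- stats::setNames(as.character(ss), ids)
  peptideSet(seqs, labs,
             name = if (is.null(name)) tools::file_path_sans_ext(basename(path)) else name,
             strict = strict, aligned = aligned)
}

#' Write a PeptideSet to FASTA
#'
#' Headers use the \code{>id|label} convention, so
#' [readFastaDataset()] round-trips the dataset.
#'
#' @param d A [PeptideSet-class].
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeFastaDataset <- function(d, path) {
  ss <- d@seqs
  names(ss) <- paste(names(ss), d@labels, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Summary statistics of a peptide dataset
#'
#' @param d A [PeptideSet-class].
#' @return A list with \code{n}, \code{n_positive}, \code{n_negative},
#'   length statistics (\code{min}/\code{mean}/\code{median}/\code{max})
#'   and \code{imbalance} = min(class counts) / n.
#' @export
datasetSummary <- function(d) {
  w <- Biostrings::width(d@seqs)
  npos <- sum(d@labels == 1L)
  nneg <- sum(d@labels == 0L)
  list(n = length(d@labels), n_positive = npos, n_negative = nneg,
       min_length = min(w), mean_length = mean(w),
       median_length = stats::median(w), max_length = max(w),
       imbalance = min(npos, nneg) / length(d@labels))
}
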