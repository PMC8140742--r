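# Tertiary-structure approximation: search each query peptide against a
# database of chains with known structures, pick the best (lowest e-value)
# hit and clip the matching residue range from the template structure.

#' Build a structure-bearing sequence database from PDB files
#'
#' Parses each file and registers one database record per chain; record ids
#' are \code{"<entry>_<chain>"} with the entry taken from the file base
#' name. Unparseable files are skipped with a message.
#'
#' @param structureFiles Character vector of PDB file paths.
#' @return An object of class \code{structureDb}: a list of records, each
#'   with \code{id}, \code{entry}, \code{chain}, \code{sequence},
#'   \code{resno} (residue numbers in author order) and \code{pdb} (the
#'   parsed \code{bio3d} object).
#' @export
buildStructureDb <- function(structureFiles) {
  if (length(structureFiles) == 0L)
    stop("fatal: no structure files given")
  records <- list()
  for (path in structureFiles) {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e) e)
    if (inherits(pdb, "error")) {
      message(sprintf("skipping unparseable structure %s: %s", path,
                      conditionMessage(pdb)))
      next
    }
    entry <- tools::file_path_sans_ext(basename(path))
    ca <- pdb$atom[pdb$atom$elety == "CA" & pdb$atom$type == "ATOM", ]
    for (ch in unique(ca$chain)) {
      cac <- ca[ca$chain == ch, ]
      # insertion codes resolved by author order: residues taken as listed
      seq1 <- paste(bio3d::aa321(cac$resid), collapse = "")
      records[[length(records) + 1L]] <- list(
        id = paste(entry, ch, sep = "_"), entry = entry, chain = ch,
        sequence = seq1, resno = cac$resno, pdb = pdb)
    }
  }
  if (length(records) == 0L)
    stop("fatal: structure database is empty (no parseable chains)")
  names(records) <- vapply(records, `[[`, character(1), "id")
  message(sprintf("structure database: %d chain record(s)", length(records)))
  structure(records, class = "structureDb")
}

#' Deterministic exact-substring search backend
#'
#' The test/offline stand-in for an external BLAST-compatible engine: a hit
#' is reported wherever the full query occurs as an exact substring of a
#' database chain, with a pseudo e-value decreasing in match length
#' (\code{10^-min(L, 200)}) and 100% identity. A backend is any function
#' \code{f(query, db)} returning a data.frame with columns \code{db_id},
#' \code{evalue}, \code{identity}, \code{query_start}, \code{query_end},
#' \code{db_start}, \code{db_end}.
#'
#' @return A backend function.
#' @export
mockSearchBackend <- function() {
  function(query, db) {
    hits <- list()
    for (rec in db) {
      at <- gregexpr(query, rec$sequence, fixed = TRUE)[[1]]
      if (at[1] == -1L) next
      L <- nchar(query)
      for (s in as.integer(at)) {
        hits[[length(hits) + 1L]] <- data.frame(
          db_id = rec$id, evalue = 10^(-min(L, 200L)), identity = 100,
          query_start = 1L, query_end = L,
          db_start = s, db_end = s + L - 1L)
      }
    }
    if (length(hits) == 0L)
      return(data.frame(db_id = character(0), evalue = numeric(0),
                        identity = numeric(0), query_start = integer(0),
                        query_end = integer(0), db_start = integer(0),
                        db_end = integer(0)))
    do.call(rbind, hits)
  }
}

# clip the db_range residues of a database chain into a ClippedStructure
.clip_hit <- function(rec, hit, query_id, query_seq) {
  rng <- hit$db_start:hit$db_end
  sub_seq <- substr(rec$sequence, hit$db_start, hit$db_end)
  resno_sel <- rec$resno[rng]
  atom <- rec$pdb$atom
  keep <- atom$type == "ATOM" & atom$chain == rec$chain &
    atom$resno %in% resno_sel
  atoms <- atom[keep, c("elety", "resid", "resno", "x", "y", "z")]
  if (!all(resno_sel %in% atoms$resno))
    stop("residues missing coordinates inside the clip")
  new("ClippedStructure", queryId = query_id, dbEntry = rec$id,
      evalue = hit$evalue, sequence = sub_seq,
      queryRange = c(as.integer(hit$query_start),
                     as.integer(hit$query_end)),
      dbRange = c(as.integer(hit$db_start), as.integer(hit$db_end)),
      atoms = atoms)
}

#' Approximate tertiary structures for a peptide dataset
#'
#' For each query sequence, runs the search backend against the database,
#' selects the best hit (lowest e-value; ties broken by higher identity,
#' then lexicographic database id) and clips the matched residue range
#' from the hit's structure. Queries without any hit, or whose clip cannot
#' be extracted, go to the omitted list; every query appears in exactly
#' one of the two outputs.
#'
#' @param d A [PeptideSet-class] of query peptides.
#' @param db A \code{structureDb} from [buildStructureDb()].
#' @param backend Search backend function; default [mockSearchBackend()].
#' @return List with \code{clips} (list of [ClippedStructure-class]) and
#'   \code{omitted} (\code{data.frame} with columns \code{id},
#'   \code{reason}).
#' @export
approximateStructures <- function(d, db, backend = mockSearchBackend()) {
  stopifnot(inherits(db, "structureDb"))
  clips <- list()
  omitted_id <- character(0)
  omitted_reason <- character(0)
  seqs <- sequences(d)
  for (qid in recordIds(d)) {
    hits <- tryCatch(backend(seqs[[qid]], db), error = function(e)
      stop(sprintf("fatal: search backend failed on query %s: %s", qid,
                   conditionMessage(e))))
    if (nrow(hits) == 0L) {
      omitted_id <- c(omitted_id, qid)
      omitted_reason <- c(omitted_reason, "no hit")
      next
    }
    hits <- hits[order(hits$evalue, -hits$identity, hits$db_id), ,
                 drop = FALSE]
    best <- hits[1L, ]
    clip <- tryCatch(
      .clip_hit(db[[best$db_id]], best, qid, seqs[[qid]]),
      error = function(e) e)
    if (inherits(clip, "error")) {
      omitted_id <- c(omitted_id, qid)
      omitted_reason <- c(omitted_reason, conditionMessage(clip))
      next
    }
    # hard assertion: clip sequence must equal the matched query part
    q_sub <- substr(seqs[[qid]], best$query_start, best$query_end)
    if (clip@sequence != q_sub) {
      omitted_id <- c(omitted_id, qid)
      omitted_reason <- c(omitted_reason,
                          sprintf("clip/query mismatch (%d mismatch(es))",
                                  sum(strsplit(clip@sequence, "")[[1]] !=
                                      strsplit(q_sub, "")[[1]])))
      next
    }
    clips[[qid]] <- clip
  }
  list(clips = clips,
       omitted = data.frame(id = omitted_id, reason = omitted_reason,
                            stringsAsFactors = FALSE))
}

#' Write a clipped structure as a PDB file
#'
#' @param clip A [ClippedStructure-class].
#' @param dir Output directory; the file is named \code{<query_id>.pdb}.
#' @return The written path, invisibly.
#' @export
writeClippedPdb <- function(clip, dir = ".") {
  path <- file.path(dir, paste0(clip@queryId, ".pdb"))
  a <- clip@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = rep("A", nrow(a)))
  invisible(path)
}

#' Write a synthetic single-chain PDB file for a peptide sequence
#'
#' Generates an idealized C-alpha helix trace for the given sequence and
#' writes it as a minimal PDB file. Synthetic: for tests and examples, not
#' a physical model.
#'
#' @param sequence One-letter amino-acid sequence.
#' @param path Output PDB path.
#' @param chain Chain identifier.
#' @return \code{path}, invisibly.
#' @export
makeSyntheticPdb <- function(sequence, path, chain = "A") {
  chars <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(all(chars %in% aminoAcids()))
  i <- seq_along(chars)
  # alpha-helix-like spiral: 100 degrees and 1.5 A rise per residue
  theta <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    i, bio3d::aa123(chars), chain, i, xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
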