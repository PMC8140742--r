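# End-to-end orchestration: fixtures/ingest -> grid expansion + filtering
# -> encoding -> cross-validation -> statistical comparison, with a run
# manifest of checksummed artifacts.

#' Read and validate a pipeline run configuration
#'
#' @param config A named list, or the path of a JSON file holding one.
#'   Recognized fields: \code{dataset} (either \code{fasta} [+
#'   \code{labels}] or synthetic-generator parameters \code{n},
#'   \code{imbalance}, \code{bias_strength}, \code{seed}, ...),
#'   \code{grids} (list of \code{group}/\code{axes} grids),
#'   \code{filter} (\code{probe_rv_threshold}), \code{cv} (\code{k},
#'   \code{repeats}, \code{seed}), \code{classifier} (\code{"rf"} or
#'   \code{"centroid"}), \code{output_dir}.
#' @return The validated configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  cv <- config$cv
  if (is.null(cv$k) || cv$k < 2L)
    stop("validation error: cv.k must be >= 2")
  if (is.null(cv$repeats) || cv$repeats < 1L)
    stop("validation error: cv.repeats must be >= 1")
  if (is.null(cv$seed) || cv$seed != as.integer(cv$seed))
    stop("validation error: cv.seed must be an integer")
  if (is.null(config$grids) || length(config$grids) == 0L)
    stop("validation error: at least one encoding grid required")
  if (is.null(config$output_dir))
    stop("validation error: output_dir required")
  if (!is.null(config$dataset$fasta) && !file.exists(config$dataset$fasta))
    stop(sprintf("validation error: dataset file not found: %s",
                 config$dataset$fasta))
  config
}

.pipeline_classifier <- function(name) {
  switch(if (is.null(name)) "rf" else name,
         rf = rfClassifier(),
         centroid = centroidClassifier(),
         stop(sprintf("validation error: unknown classifier '%s'", name)))
}

# grids as parsed from JSON (named axes lists) -> expandEncodingGrid input
.parse_grids <- function(grids) {
  lapply(grids, function(g) {
    axes <- g$axes
    if (is.null(axes)) axes <- list()
    list(group = g$group, axes = as.list(axes))
  })
}

#' Run the full benchmarking pipeline
#'
#' Executes, in order: dataset ingestion (or synthetic generation), grid
#' expansion, optional probe-based redundancy filtering, encoding,
#' repeated stratified CV over the record-id intersection of all encoded
#' datasets (so fold rows are traceable across specs), metric computation,
#' and the statistical comparison (Friedman / Iman-Davenport / Nemenyi
#' critical differences, pairwise disagreement, adjusted RV of the top
#' specs). All artifacts are written under \code{output_dir} and listed in
#' a manifest with MD5 checksums; identical configurations and seeds
#' reproduce identical checksums.
#'
#' @param config Configuration list or JSON path (see [readRunConfig()]).
#' @return The manifest, invisibly (list with \code{artifacts},
#'   \code{checksums}, \code{versions}).
#' @export
runPipeline <- function(config) {
  config <- readRunConfig(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", "pepBench", sprintf(fmt, ...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  unlink(log_path)

  # stage 1: dataset
  ds_cfg <- config$dataset
  d <- if (!is.null(ds_cfg$fasta)) {
    logf("reading dataset from %s", ds_cfg$fasta)
    readFastaDataset(ds_cfg$fasta, labels = ds_cfg$labels)
  } else {
    logf("generating synthetic dataset (n = %d)", ds_cfg$n)
    generateSyntheticDataset(
      n = ds_cfg$n,
      imbalance = if (is.null(ds_cfg$imbalance)) 0.5 else ds_cfg$imbalance,
      lengthRange = if (is.null(ds_cfg$length_range)) c(3L, 255L)
                    else ds_cfg$length_range,
      biasStrength = if (is.null(ds_cfg$bias_strength)) 0.3
                     else ds_cfg$bias_strength,
      seed = if (is.null(ds_cfg$seed)) config$cv$seed else ds_cfg$seed)
  }
  fasta_path <- file.path(out, "dataset.fasta")
  writeFastaDataset(d, fasta_path)
  artifacts <- fasta_path

  # stage 2: grid expansion and filtering
  specs <- expandEncodingGrid(.parse_grids(config$grids))
  logf("expanded %d encoding spec(s)", length(specs))
  thr <- config$filter$probe_rv_threshold
  if (!is.null(thr)) {
    specs <- filterSpecsByProbe(specs, d, threshold = thr)
    logf("%d spec(s) retained after redundancy filtering", length(specs))
  }
  specs_path <- file.path(out, "specs.json")
  jsonlite::write_json(
    lapply(specs, function(s) list(group = s@group, params = s@params)),
    specs_path, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, specs_path)

  # stage 3: encoding
  encoded <- list()
  for (spec in specs) {
    enc <- tryCatch(encodeDataset(d, spec), error = function(e) e)
    if (inherits(enc, "error")) {
      logf("encoding %s failed: %s", specId(spec), conditionMessage(enc))
      next
    }
    encoded[[specId(spec)]] <- enc
    p <- file.path(out, paste0("encoded_", make.names(specId(spec)), ".csv"))
    writeEncodedSet(enc, p)
    artifacts <- c(artifacts, p, paste0(p, ".json"))
  }
  if (length(encoded) == 0L) stop("runtime error: no spec encoded the dataset")

  # stage 4: paired CV over the record intersection of all encodings
  shared <- Reduce(intersect, lapply(encoded, recordIds))
  labels <- classLabels(d)[shared]
  logf("cross-validating %d spec(s) on %d shared record(s)",
       length(encoded), length(shared))
  parts <- .make_partitions(shared, labels, config$cv$k, config$cv$repeats,
                            config$cv$seed)
  classifier <- .pipeline_classifier(config$classifier)
  cvs <- lapply(encoded, function(e)
    .run_cv(featureMatrix(e)[shared, , drop = FALSE], labels, parts,
            classifier, config$cv$seed, e@spec))
  metrics <- lapply(cvs, computeMetrics)
  metrics_path <- file.path(out, "metrics.csv")
  writeMetricsCsv(do.call(rbind, metrics), metrics_path)
  artifacts <- c(artifacts, metrics_path)

  # stage 5: statistical comparison
  comparison <- list(
    mean_f1 = as.list(vapply(metrics, function(m) mean(m$F1), numeric(1))))
  if (length(cvs) >= 2L) {
    f1_by_fold <- vapply(metrics, function(m) m$F1,
                         numeric(nrow(metrics[[1]])))
    ranks <- rankMatrix(f1_by_fold)
    chi2 <- friedmanStatistic(ranks)
    idv <- imanDavenport(chi2, nrow(ranks), ncol(ranks))
    cd_pairs <- criticalDifferencePairs(ranks)
    sim <- pairwiseSimilarity(cvs, "disagreement")
    ktop <- min(length(encoded), 10L)
    rv <- topKCorrelation(metrics, unname(encoded), ktop)
    comparison <- c(comparison, list(
      friedman_chi2 = chi2, iman_davenport = idv,
      critical_difference = cd_pairs,
      disagreement = as.data.frame(as.table(sim)),
      rv_top = as.data.frame(as.table(rv))))
  }
  cmp_path <- file.path(out, "comparison.json")
  jsonlite::write_json(comparison, cmp_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  artifacts <- c(artifacts, cmp_path)

  manifest <- list(
    artifacts = basename(artifacts),
    checksums = unname(tools::md5sum(artifacts)),
    versions = list(pepBench = as.character(utils::packageVersion("pepBench")),
                    R = as.character(getRversion())))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  logf("run complete: %d artifact(s)", length(artifacts))
  invisible(manifest)
}
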