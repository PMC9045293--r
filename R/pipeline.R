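# Run orchestration: configuration, the per-sample pipeline, and the
# batch commands (identify, classify, simulate) behind the CLI script.

#' Run configuration
#'
#' Bundles every tunable of the pipeline.  The defaults are the validated
#' parameter set: automated trimming at mean QV 40 over a 10-bp window
#' with minimum clear length 20; manual profile at 15\% low-QV / 10\%
#' undetermined / clear length 50 / 20 mixed bases; secondary-peak ratio
#' 0.33; decision thresholds 0.8 / 99 / 97 / 98 / 440 / 400.
#'
#' @param primaryDb A \linkS4class{ReferenceDB} (primary 16S tier), or
#'   \code{NULL} if set later.
#' @param broadDb Optional fallback \linkS4class{ReferenceDB}.
#' @param profile Trimming profile used by the pipeline,
#'   \code{"automated"} (default) or \code{"manual"}.
#' @param trim,manualTrim \code{\link{trimParams}} for the two profiles.
#' @param scoring \code{\link{alignScoring}} for all alignments.
#' @param thresholds \code{\link{idThresholds}} for classification.
#' @param topN Hits kept per search.
#' @param outputDir Where reports are written.
#' @param seed Seed for anything stochastic (simulation).
#' @param logLevel \code{"quiet"}, \code{"info"} or \code{"debug"}.
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(primaryDb = NULL, broadDb = NULL,
                      profile = c("automated", "manual"),
                      trim = trimParams("automated"),
                      manualTrim = trimParams("manual"),
                      scoring = alignScoring(),
                      thresholds = idThresholds(),
                      topN = 50L, outputDir = ".", seed = 1L,
                      logLevel = "info") {
  structure(list(primaryDb = primaryDb, broadDb = broadDb,
                 profile = match.arg(profile), trim = trim,
                 manualTrim = manualTrim, scoring = scoring,
                 thresholds = thresholds, topN = as.integer(topN),
                 outputDir = outputDir, seed = as.integer(seed),
                 logLevel = logLevel),
            class = "RunConfig")
}

.log <- function(config, level, fmt, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[config$logLevel]] >= levels[[level]])
    message(sprintf(fmt, ...))
}

.trimFor <- function(config) {
  if (config$profile == "manual") config$manualTrim else config$trim
}

.trimWith <- function(read, config) {
  if (config$profile == "manual")
    trimManualProfile(read, config$manualTrim)
  else trimSlidingWindow(read, config$trim)
}

#' Identify one sample from its reads
#'
#' The per-sample pipeline: mixed-base calling (when traces are present),
#' quality trimming, read QC, consensus merge (with automatic single-read
#' fallback), length QC, database search with broad-tier fallback, and
#' classification.
#'
#' @param fwd Forward \linkS4class{SangerRead}, or \code{NULL}.
#' @param rev Reverse \linkS4class{SangerRead}, or \code{NULL}.
#' @param config A \code{\link{runConfig}} with \code{primaryDb} set.
#' @return List with \code{result} (\linkS4class{IdentificationResult}),
#'   \code{record} (the query \linkS4class{ConsensusRecord} or NULL),
#'   \code{hitTable} (or NULL), \code{tier}, and \code{upstream} (QC facts
#'   for reporting).
#' @export
identifyFromReads <- function(fwd, rev, config) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(config$primaryDb))
    stop("configuration error: no primary reference database")
  tp <- .trimFor(config)

  prep <- function(read) {
    if (is.null(read)) return(NULL)
    read <- callMixedBases(read, tp)
    win <- .trimWith(read, config)
    qc <- readQC(read, win, tp)
    .log(config, "debug", "%s %s: window [%d,%d], mean QV %.1f -> %s",
         sampleId(read), direction(read), win@start, win@end, win@meanQV,
         if (qc$pass) "pass" else paste(qc$reasons, collapse = "; "))
    list(read = read, trimmed = trimRead(read, win), win = win, qc = qc)
  }
  f <- prep(fwd); r <- prep(rev)
  up <- list(
    fwdQc = if (is.null(f)) "missing" else if (f$qc$pass) "pass" else "fail",
    revQc = if (is.null(r)) "missing" else if (r$qc$pass) "pass" else "fail")

  passed <- list()
  if (!is.null(f) && f$qc$pass) passed <- c(passed, list(f))
  if (!is.null(r) && r$qc$pass) passed <- c(passed, list(r))

  if (!length(passed)) {
    reasons <- c(if (!is.null(f)) paste("forward:",
                   paste(f$qc$reasons, collapse = "; ")),
                 if (!is.null(r)) paste("reverse:",
                   paste(r$qc$reasons, collapse = "; ")))
    return(list(result = excludedResult(c("read QC failed", reasons)),
                record = NULL, hitTable = NULL, tier = NA_character_,
                upstream = up))
  }

  record <- NULL
  if (length(passed) == 2L) {
    record <- tryCatch(
      mergeReads(passed[[1L]]$trimmed, passed[[2L]]$trimmed,
                 scoring = config$scoring),
      error = function(e) NULL)
    if (is.null(record)) {
      .log(config, "info", "%s: reads do not form a contig; using best single read",
           sampleId(passed[[1L]]$read))
      best <- passed[[which.max(vapply(passed, function(p) p$qc$meanQV,
                                       numeric(1)))]]
      record <- singleReadRecord(best$trimmed)
    }
  } else {
    record <- singleReadRecord(passed[[1L]]$trimmed)
  }
  up$provenance <- provenance(record)
  up$consensusLength <- length(record)
  up$lengthCategory <- lengthCategory(record)
  up$overlapLength <- record@overlapLength
  up$nDisagreements <- record@nDisagreements

  if (lengthCategory(record) == "short") {
    .log(config, "info", "%s: %d bp consensus (<400 bp), excluded from search",
         sampleId(record), length(record))
    return(list(result = excludedResult(sprintf(
                  "consensus %d bp < 400 bp (short sequence)",
                  length(record))),
                record = record, hitTable = NULL, tier = NA_character_,
                upstream = up))
  }

  fb <- fallbackSearch(record, config$primaryDb, config$broadDb,
                       topN = config$topN, scoring = config$scoring,
                       thresholds = config$thresholds)
  .log(config, "info", "%s: %s (%s)%s", sampleId(record),
       reportedName(fb$result), category(fb$result),
       if (nzchar(fb$note)) paste0(" [", fb$note, "]") else "")
  list(result = fb$result, record = record, hitTable = fb$hitTable,
       tier = fb$tier, upstream = up)
}

.readManifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (!file.exists(manifest))
      stop("configuration error: manifest not found: ", manifest)
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE,
                                  colClasses = "character")
  }
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  need <- c("sample_id", "forward", "reverse")
  if (!all(need %in% names(manifest)))
    stop("configuration error: manifest needs columns ",
         paste(need, collapse = ", "))
  manifest
}

#' Batch identification from a sample manifest
#'
#' Runs the full pipeline for every sample of a manifest (columns
#' \code{sample_id}, \code{forward}, \code{reverse}; paths to .ab1 files,
#' empty/NA when a direction is missing).  Per-sample failures (unreadable
#' files, failed QC) are recorded in the report, never raised; only
#' configuration problems (missing database, bad manifest) raise errors.
#'
#' @param manifest data.frame or path to a header-ed TSV.
#' @param config A \code{\link{runConfig}} with \code{primaryDb} set.
#' @return The report data.frame (one row per sample), invisibly;
#'   \code{report.tsv} and \code{report.json} are written to
#'   \code{config$outputDir}.
#' @export
cmdIdentify <- function(manifest, config) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(config$primaryDb))
    stop("configuration error: no primary reference database")
  manifest <- .readManifest(manifest)

  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    loadRead <- function(path, dirn) {
      if (is.na(path) || !nzchar(path)) return(NULL)
      readABIF(path, direction = dirn, sampleId = sid)
    }
    row <- tryCatch({
      fwd <- loadRead(manifest$forward[i], "forward")
      rev <- loadRead(manifest$reverse[i], "reverse")
      if (is.null(fwd) && is.null(rev))
        stop("no reads supplied")
      out <- identifyFromReads(fwd, rev, config)
      renderReportRow(out$result, sid, out$upstream)
    }, error = function(e) {
      .log(config, "info", "%s: excluded: read error (%s)", sid,
           conditionMessage(e))
      renderReportRow(excludedResult(paste("read error:",
                                           conditionMessage(e))), sid)
    })
    rows[[i]] <- row
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    renderReportRow(excludedResult("x"), "x")[0, ]
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report, file.path(config$outputDir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(config$outputDir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(report)
}

#' Classify a table of pre-computed metrics
#'
#' Applies the decision algorithm row-wise to a table of alignment
#' metrics, e.g. exported from an external BLAST run.  Expected columns:
#' \code{sample_id, top_genus, top_species, group, aligned_length,
#' query_cover, percent_identity, distance_next_species} (group and
#' distance may be empty/NA).  Malformed rows produce row-level error
#' records; the run continues.
#'
#' @param metricsTable data.frame or path to a header-ed TSV.
#' @param thresholds \code{\link{idThresholds}}.
#' @param out Optional path for a TSV copy of the report.
#' @return data.frame with the input metrics plus \code{category},
#'   \code{reported_name}, \code{comment}, \code{qc_reasons},
#'   \code{error}.
#' @export
cmdClassify <- function(metricsTable, thresholds = idThresholds(),
                        out = NULL) {
  if (is.character(metricsTable) && length(metricsTable) == 1L) {
    if (!file.exists(metricsTable))
      stop("configuration error: metrics table not found: ", metricsTable)
    metricsTable <- utils::read.delim(metricsTable,
                                      stringsAsFactors = FALSE)
  }
  tab <- as.data.frame(metricsTable, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    rows[[i]] <- tryCatch({
      r <- tab[i, ]
      num <- function(x) suppressWarnings(as.numeric(x))
      m <- idMetrics(
        alignedLength = num(r$aligned_length),
        queryCover = num(r$query_cover),
        percentIdentity = num(r$percent_identity),
        distanceNextSpecies = num(r$distance_next_species),
        topGenus = as.character(r$top_genus),
        topSpecies = as.character(r$top_species),
        topGroup = if (is.null(r$group)) NA_character_
                   else as.character(r$group))
      if (anyNA(c(m$alignedLength, m$queryCover, m$percentIdentity)))
        stop("non-numeric metric")
      res <- classify(m, thresholds = thresholds)
      data.frame(sample_id = as.character(r$sample_id),
                 category = category(res),
                 reported_name = reportedName(res),
                 comment = res@comment,
                 qc_reasons = paste(qcReasons(res), collapse = "; "),
                 error = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(sample_id = as.character(tab$sample_id[i]),
                 category = NA_character_, reported_name = NA_character_,
                 comment = NA_character_, qc_reasons = NA_character_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), category = character(0),
               reported_name = character(0), comment = character(0),
               qc_reasons = character(0), error = character(0),
               stringsAsFactors = FALSE)
  if (!is.null(out))
    utils::write.table(report, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  report
}

#' Write a simulated fixture directory
#'
#' Generates the reference database files and, for \code{nSamples}
#' samples, forward/reverse .ab1 chromatograms plus a manifest, ready to
#' feed to \code{\link{cmdIdentify}}.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param dir Output directory.
#' @param nSamples Number of simulated samples.
#' @param withTraces Synthesize trace data in the .ab1 files.
#' @return The manifest data.frame, invisibly.
#' @export
cmdSimulate <- function(cfg, dir, nSamples = 2L, withTraces = FALSE) {
  stopifnot(inherits(cfg, "SimConfig"))
  gen <- generateReferenceDB(cfg, dir = dir)
  pick <- sample.int(nrow(gen$truth), nSamples, replace = TRUE)
  seeds <- sample.int(2^30, nSamples)
  rows <- vector("list", nSamples)
  for (s in seq_len(nSamples)) {
    sid <- sprintf("sim%03d", s)
    pair <- simulateReadPair(gen$truth$sequence[pick[s]], cfg,
                             sampleId = sid, seed = seeds[s],
                             withTraces = withTraces)
    fPath <- file.path(dir, paste0(sid, "_F.ab1"))
    rPath <- file.path(dir, paste0(sid, "_R.ab1"))
    writeABIF(pair$forward, fPath)
    writeABIF(pair$reverse, rPath)
    rows[[s]] <- data.frame(sample_id = sid, forward = fPath,
                            reverse = rPath,
                            truth_genus = gen$truth$genus[pick[s]],
                            truth_species = gen$truth$species[pick[s]],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest[, c("sample_id", "forward", "reverse")],
                     file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
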