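# Reference search: affine-gap local alignment against every database
# record, alignment metrics at BLAST-like precision, distance to the next
# species, BLAST tabular ingestion, and the broad-database fallback.

#' Alignment scoring parameters
#'
#' Defaults approximate nucleotide-BLAST behaviour: match +1, mismatch -2,
#' gap opening 5 and gap extension 2 (a gap of length L costs
#' \code{gapOpening + L * gapExtension}).
#'
#' @param match,mismatch Substitution scores (exact letter equality only;
#'   ambiguity codes never fuzzy-match).
#' @param gapOpening,gapExtension Affine gap costs (positive numbers).
#' @return A list of class \code{"AlignScoring"}.
#' @export
alignScoring <- function(match = 1, mismatch = -2,
                         gapOpening = 5, gapExtension = 2) {
  structure(list(match = match, mismatch = mismatch,
                 gapOpening = gapOpening, gapExtension = gapExtension),
            class = "AlignScoring")
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment under affine-gap scoring (Gotoh), with
#' the conventional empty-alignment floor at score 0 and a deterministic
#' traceback (diagonal preferred over gaps on ties; the best cell with the
#' smallest query, then subject, index starts the traceback).  Letters
#' match only on exact equality; ambiguity codes never fuzzy-match.
#'
#' @param query,subject DNA strings (IUPAC uppercase), non-empty.
#' @param scoring \code{\link{alignScoring}} parameters.
#' @return List with \code{score}, \code{matches} (identical columns),
#'   \code{alignedLength} (alignment columns, gaps included),
#'   \code{queryStart}, \code{queryEnd} (1-based span on the query),
#'   \code{percentIdentity} (one decimal).  A degenerate score-0 alignment
#'   reports \code{alignedLength = 0}.
#' @export
localAlign <- function(query, subject, scoring = alignScoring()) {
  query <- toupper(as.character(query))
  subject <- toupper(as.character(subject))
  stopifnot(nchar(query) > 0L, nchar(subject) > 0L)
  a <- .localAlignCpp(query, subject, scoring$match, scoring$mismatch,
                      scoring$gapOpening, scoring$gapExtension)
  a$percentIdentity <- if (a$alignedLength > 0L)
    .roundHalfUp(100 * a$matches / a$alignedLength, 1L) else NA_real_
  a
}

#' Search a query against a reference database
#'
#' Aligns the consensus (or single-read) query against every record of the
#' database and returns the ranked hit table.  Queries in the
#' \code{"short"} length category (<400 bp) are refused: they are excluded
#' from the search stage by QC policy.
#'
#' @param record A \linkS4class{ConsensusRecord} (or a plain character
#'   query, in which case no length check applies and \code{queryId} must
#'   be given).
#' @param db A \linkS4class{ReferenceDB}.
#' @param topN Number of hits to keep (default 50).
#' @param scoring \code{\link{alignScoring}} parameters.
#' @param queryId Query identifier when \code{record} is a plain string.
#' @return A \linkS4class{HitTable} sorted by score, then percent identity,
#'   then accession.
#' @export
searchDatabase <- function(record, db, topN = 50L,
                           scoring = alignScoring(), queryId = NULL) {
  stopifnot(is(db, "ReferenceDB"))
  if (length(db) == 0L) stop("reference database is empty")
  if (is(record, "ConsensusRecord")) {
    if (lengthCategory(record) == "short")
      stop("query is in the short (<400 bp) category and is excluded ",
           "from the database search")
    query <- consensusSequence(record)
    queryId <- sampleId(record)
  } else {
    query <- toupper(as.character(record))
    if (is.null(queryId)) stop("queryId required for a plain-string query")
  }
  qlen <- nchar(query)
  accs <- names(db@sequences)
  tax <- taxonomy(db)
  rows <- vector("list", length(accs))
  for (k in seq_along(accs)) {
    a <- localAlign(query, as.character(db@sequences[[k]]), scoring)
    if (a$alignedLength == 0L) next
    t <- tax[match(accs[k], tax$accession), ]
    rows[[k]] <- data.frame(
      accession = accs[k], genus = t$genus, species = t$species,
      group = t$group, alignedLength = a$alignedLength,
      percentIdentity = a$percentIdentity,
      queryCover = .roundHalfUp(100 * (a$queryEnd - a$queryStart + 1L) /
                                qlen, 0L),
      score = a$score, stringsAsFactors = FALSE)
  }
  h <- do.call(rbind, c(list(.emptyHits()), rows[!vapply(rows, is.null,
                                                          logical(1))]))
  h <- .sortHits(h)
  if (nrow(h) > topN) h <- h[seq_len(topN), , drop = FALSE]
  HitTable(queryId, h, dbTier = dbTier(db))
}

#' Parse BLAST tabular (outfmt-6-style) hits
#'
#' Expected tab-separated columns: query id, subject accession, percent
#' identity, alignment length, query start, query end, e-value, bit score.
#' Query cover is computed from the query span and the full query length,
#' which is taken from a \code{"# query_length: N"} comment line or the
#' \code{queryLength} argument.
#'
#' @param path Path to the tabular hit file.
#' @param taxonomy Taxonomy data.frame (see \code{\link{readTaxonomy}}).
#'   Hits whose accession has no taxonomy entry are kept with genus and
#'   species \code{"unknown"}, with a warning.
#' @param queryLength Full (trimmed) query length in bases; overrides any
#'   header comment.
#' @param dbTier Tier label to record on the table.
#' @return A \linkS4class{HitTable}.
#' @export
parseBlastTabular <- function(path, taxonomy, queryLength = NULL,
                              dbTier = "primary_16S") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#\\s*query_length:", lines, value = TRUE)
  if (is.null(queryLength) && length(hdr))
    queryLength <- as.integer(sub("^#\\s*query_length:\\s*", "", hdr[1L]))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(HitTable("query", dbTier = dbTier))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(f, length, integer(1)) < 8L))
    stop("expected at least 8 tab-separated columns: ", path)
  qid <- vapply(f, `[[`, character(1), 1L)
  acc <- vapply(f, `[[`, character(1), 2L)
  pid <- as.numeric(vapply(f, `[[`, character(1), 3L))
  alen <- as.integer(vapply(f, `[[`, character(1), 4L))
  qs <- as.integer(vapply(f, `[[`, character(1), 5L))
  qe <- as.integer(vapply(f, `[[`, character(1), 6L))
  bit <- as.numeric(vapply(f, `[[`, character(1), 8L))
  if (is.null(queryLength))
    stop("query length not given and no '# query_length:' header found")

  idx <- match(acc, taxonomy$accession)
  if (anyNA(idx))
    warning("no taxonomy entry for accession(s): ",
            paste(unique(acc[is.na(idx)]), collapse = ", "))
  genus <- ifelse(is.na(idx), "unknown", taxonomy$genus[idx])
  species <- ifelse(is.na(idx), "unknown", taxonomy$species[idx])
  group <- ifelse(is.na(idx), NA_character_, taxonomy$group[idx])

  h <- data.frame(accession = acc, genus = genus, species = species,
                  group = group, alignedLength = alen,
                  percentIdentity = pid,
                  queryCover = .roundHalfUp(
                    100 * (pmax(qs, qe) - pmin(qs, qe) + 1L) / queryLength,
                    0L),
                  score = bit, stringsAsFactors = FALSE)
  HitTable(qid[1L], h, dbTier = dbTier)
}

# species key used for distance computation: the group label (species
# complex) stands in for the binomial when present
.speciesKey <- function(h) {
  ifelse(!is.na(h$group) & nzchar(h$group), h$group,
         paste(h$genus, h$species))
}

#' Distance to the next species
#'
#' The separation, in percentage points of identity, between the
#' best-matching species and the nearest hit of a different species:
#' (best percent identity of the top species) minus (best percent identity
#' among hits of any other species).  Hits sharing a species-group label
#' count as one species.  \code{NA} when the table contains no other
#' species.
#'
#' The top species is the species achieving the highest percent identity
#' in the table (ties broken by hit rank), so the distance is never
#' negative.
#'
#' @param hitTable A non-empty \linkS4class{HitTable}.
#' @return List with \code{value} (percentage points, one decimal, or NA),
#'   \code{topSpecies}, \code{nextSpecies} (NA when absent).
#' @export
distanceToNextSpecies <- function(hitTable) {
  stopifnot(is(hitTable, "HitTable"))
  h <- hits(hitTable)
  if (!nrow(h)) stop("hit table is empty")
  key <- .speciesKey(h)
  bestId <- tapply(h$percentIdentity, key, max)
  # top species: highest best-identity, ties resolved by hit rank
  topId <- max(h$percentIdentity)
  topKey <- key[which(h$percentIdentity == topId)[1L]]
  other <- h[key != topKey, , drop = FALSE]
  if (!nrow(other))
    return(list(value = NA_real_, topSpecies = topKey,
                nextSpecies = NA_character_))
  nextId <- max(other$percentIdentity)
  nextKey <- .speciesKey(other)[which(other$percentIdentity == nextId)[1L]]
  list(value = .roundHalfUp(bestId[[topKey]] - nextId, 1L),
       topSpecies = topKey, nextSpecies = nextKey)
}

#' Decision metrics from a hit table
#'
#' Collapses a ranked hit table to the four decision metrics: aligned query
#' length, query cover and percent identity of the best hit of the top
#' species, plus the distance to the next species.
#'
#' @param hitTable A non-empty \linkS4class{HitTable}.
#' @return A named list (see \code{\link{classify}}).
#' @export
hitMetrics <- function(hitTable) {
  h <- hits(hitTable)
  if (!nrow(h)) stop("hit table is empty")
  d <- distanceToNextSpecies(hitTable)
  key <- .speciesKey(h)
  topHits <- h[key == d$topSpecies, , drop = FALSE]
  best <- topHits[order(-topHits$percentIdentity, -topHits$score,
                        topHits$accession), , drop = FALSE][1L, ]
  list(alignedLength = best$alignedLength,
       queryCover = best$queryCover,
       percentIdentity = best$percentIdentity,
       distanceNextSpecies = d$value,
       topGenus = best$genus, topSpecies = best$species,
       topGroup = best$group, topAccession = best$accession,
       dbTier = dbTier(hitTable))
}

#' Broad-database fallback search
#'
#' When the primary 16S tier yields an inconclusive classification
#' (typically because a few terminal bases are not covered by the curated
#' references), the query is re-searched against a broader nucleotide
#' database.  The primary tier is preferred whenever it is conclusive.
#'
#' @param record The query \linkS4class{ConsensusRecord}.
#' @param primaryDb The primary 16S \linkS4class{ReferenceDB}.
#' @param broadDb Optional broad-tier \linkS4class{ReferenceDB}; when
#'   \code{NULL} the primary result is returned unchanged with a note.
#' @param topN,scoring Passed to \code{\link{searchDatabase}}.
#' @param thresholds Decision thresholds (see \code{\link{idThresholds}}).
#' @return List with \code{hitTable}, \code{result}
#'   (\linkS4class{IdentificationResult}), \code{tier} and \code{note}.
#' @export
fallbackSearch <- function(record, primaryDb, broadDb = NULL, topN = 50L,
                           scoring = alignScoring(),
                           thresholds = idThresholds()) {
  ht <- searchDatabase(record, primaryDb, topN = topN, scoring = scoring)
  res <- classify(hitMetrics(ht), thresholds = thresholds)
  if (category(res) != "inconclusive")
    return(list(hitTable = ht, result = res, tier = dbTier(primaryDb),
                note = ""))
  if (is.null(broadDb))
    return(list(hitTable = ht, result = res, tier = dbTier(primaryDb),
                note = "inconclusive at primary tier; no broad database configured"))
  ht2 <- searchDatabase(record, broadDb, topN = topN, scoring = scoring)
  res2 <- classify(hitMetrics(ht2), thresholds = thresholds)
  if (category(res2) != "inconclusive")
    return(list(hitTable = ht2, result = res2, tier = dbTier(broadDb),
                note = "resolved at broad tier"))
  list(hitTable = ht2, result = res2, tier = dbTier(broadDb),
       note = "inconclusive at both tiers")
}
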