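# The decision algorithm: thresholds on distance to next species, percent
# identity, query cover and aligned query length determine whether a
# sample is reported to species level, genus level, or as inconclusive.

#' Decision thresholds
#'
#' Defaults follow CLSI-style interpretive criteria for partial 16S
#' sequences: species-level reporting requires distance to the next
#' species >= 0.8 percentage points, identity >= 99\%, query cover >=
#' 98\% and aligned query length > 440 bp; genus-level reporting accepts
#' identity in [97, 99) or an unresolved distance; aligned lengths of
#' 400--440 bp are reportable at most to genus (cover >= 98 and identity
#' >= 99); below 400 bp the sequence is too short.
#'
#' @param distSpecies Minimum distance to the next species (percentage
#'   points) for a species-level call.
#' @param idSpecies Minimum percent identity for species- (and uncapped
#'   genus-) level calls.
#' @param idGenusMin Minimum percent identity for a genus-level call.
#' @param coverMin Minimum query cover (percent).
#' @param longMin Aligned length (bp) strictly above which full species
#'   reporting is allowed.
#' @param mediumMin Aligned length (bp) at or above which genus-capped
#'   reporting is allowed.
#' @return A list of class \code{"IdThresholds"}.
#' @export
idThresholds <- function(distSpecies = 0.8, idSpecies = 99,
                         idGenusMin = 97, coverMin = 98,
                         longMin = 440L, mediumMin = 400L) {
  structure(list(distSpecies = distSpecies, idSpecies = idSpecies,
                 idGenusMin = idGenusMin, coverMin = coverMin,
                 longMin = as.integer(longMin),
                 mediumMin = as.integer(mediumMin)),
            class = "IdThresholds")
}

#' Assemble decision metrics
#'
#' @param alignedLength Aligned query length (bp).
#' @param queryCover Query cover (percent).
#' @param percentIdentity Percent identity to the best reference.
#' @param distanceNextSpecies Distance to the next species (percentage
#'   points) or NA when no other species was hit.
#' @param topGenus,topSpecies Genus and species epithet of the top hit.
#' @param topGroup Optional species-group label (reported in place of the
#'   binomial).
#' @param topAccession Optional accession of the top hit.
#' @param dbTier Database tier the metrics came from.
#' @return A named list suitable for \code{\link{classify}}.
#' @export
idMetrics <- function(alignedLength, queryCover, percentIdentity,
                      distanceNextSpecies = NA_real_,
                      topGenus = NA_character_, topSpecies = NA_character_,
                      topGroup = NA_character_,
                      topAccession = NA_character_,
                      dbTier = "primary_16S") {
  list(alignedLength = as.numeric(alignedLength),
       queryCover = as.numeric(queryCover),
       percentIdentity = as.numeric(percentIdentity),
       distanceNextSpecies = as.numeric(distanceNextSpecies),
       topGenus = topGenus, topSpecies = topSpecies, topGroup = topGroup,
       topAccession = topAccession, dbTier = dbTier)
}

.genusName <- function(m) {
  if (!is.null(m$topGroup) && !is.na(m$topGroup) && nzchar(m$topGroup))
    m$topGroup
  else paste0(m$topGenus, " sp.")
}

.closestComment <- function(m) {
  if (is.na(m$topGenus) || is.na(m$topSpecies)) ""
  else sprintf("most closely related to %s %s", m$topGenus, m$topSpecies)
}

#' Classify decision metrics to a final identification
#'
#' Total decision function over the metric space.  For aligned length
#' > 440 bp: species when distance >= 0.8, identity >= 99 and cover >= 98;
#' genus when cover >= 98 and either identity in [97, 99) or identity
#' >= 99 with distance < 0.8 (or distance not measurable); inconclusive
#' when cover < 98 or identity < 97.  For aligned length 400--440 bp:
#' genus when cover >= 98 and identity >= 99, else inconclusive.  Below
#' 400 bp: inconclusive (short sequence).  An unmeasurable (NA) distance
#' caps the call at genus.  \code{qcReasons} lists every criterion that
#' failed or capped the call.
#'
#' @param m Metrics from \code{\link{idMetrics}} or
#'   \code{\link{hitMetrics}} (a named list; a one-row data.frame also
#'   works).
#' @param thresholds \code{\link{idThresholds}}.
#' @return An \linkS4class{IdentificationResult}.
#' @export
classify <- function(m, thresholds = idThresholds()) {
  if (is.data.frame(m)) m <- as.list(m[1L, ])
  need <- c("alignedLength", "queryCover", "percentIdentity",
            "distanceNextSpecies")
  stopifnot(all(need %in% names(m)))
  th <- thresholds
  alen <- m$alignedLength; cov <- m$queryCover
  pid <- m$percentIdentity; dist <- m$distanceNextSpecies
  reasons <- character(0)

  if (alen < th$mediumMin) {
    cat_ <- "inconclusive"
    reasons <- sprintf("aligned query length < %d bp (short sequence)",
                       th$mediumMin)
  } else if (alen <= th$longMin) {
    capNote <- sprintf(
      "aligned query length %d-%d bp: species-level identification not permitted",
      th$mediumMin, th$longMin)
    if (cov >= th$coverMin && pid >= th$idSpecies) {
      cat_ <- "genus"
      reasons <- capNote
    } else {
      cat_ <- "inconclusive"
      reasons <- capNote
      if (cov < th$coverMin)
        reasons <- c(reasons, sprintf("query cover < %s", th$coverMin))
      if (pid < th$idSpecies)
        reasons <- c(reasons, sprintf("%% identity < %s", th$idSpecies))
    }
  } else if (cov < th$coverMin) {
    cat_ <- "inconclusive"
    reasons <- sprintf("query cover < %s", th$coverMin)
  } else if (pid < th$idGenusMin) {
    cat_ <- "inconclusive"
    reasons <- sprintf("%% identity < %s", th$idGenusMin)
  } else if (pid < th$idSpecies) {
    cat_ <- "genus"
    reasons <- sprintf("%% identity < %s", th$idSpecies)
  } else if (is.na(dist)) {
    cat_ <- "genus"
    reasons <- "distance to next species not measurable"
  } else if (dist < th$distSpecies) {
    cat_ <- "genus"
    reasons <- sprintf("distance to next species < %s", th$distSpecies)
  } else {
    cat_ <- "species"
  }

  name <- switch(cat_,
    species = paste(m$topGenus, m$topSpecies),
    genus = .genusName(m),
    "Inconclusive")
  comment <- if (cat_ == "genus") .closestComment(m) else ""
  new("IdentificationResult", category = cat_, reportedName = name,
      comment = comment, qcReasons = reasons,
      metrics = m[intersect(c("alignedLength", "queryCover",
                              "percentIdentity", "distanceNextSpecies",
                              "topGenus", "topSpecies", "topGroup",
                              "topAccession", "dbTier"), names(m))])
}

#' Mark a sample as excluded before classification
#'
#' Used when a sample never reaches the search stage (unreadable file,
#' failed read QC, or a short consensus).
#'
#' @param reason Why the sample was excluded.
#' @return An \linkS4class{IdentificationResult} with category
#'   \code{"excluded"} and blank metrics.
#' @export
excludedResult <- function(reason) {
  new("IdentificationResult", category = "excluded",
      reportedName = "Excluded", comment = "",
      qcReasons = as.character(reason),
      metrics = idMetrics(NA_real_, NA_real_, NA_real_))
}

#' Render one flat report row
#'
#' @param result An \linkS4class{IdentificationResult}.
#' @param sampleId Sample identifier.
#' @param upstream Optional list of upstream QC facts: \code{fwdQc},
#'   \code{revQc} ("pass"/"fail"/"missing"), \code{provenance},
#'   \code{consensusLength}, \code{lengthCategory}, \code{overlapLength},
#'   \code{nDisagreements}.
#' @return A one-row data.frame with fixed columns (sample_id, read QC per
#'   direction, provenance, consensus length and category, top hit, the
#'   four decision metrics, database tier, category, reported name,
#'   comment, QC reasons).
#' @export
renderReportRow <- function(result, sampleId, upstream = list()) {
  stopifnot(is(result, "IdentificationResult"))
  m <- metrics(result)
  g <- function(x, d = NA) if (is.null(upstream[[x]])) d else upstream[[x]]
  v <- function(x) if (is.null(m[[x]]) || length(m[[x]]) == 0L) NA else m[[x]]
  data.frame(
    sample_id = sampleId,
    fwd_qc = as.character(g("fwdQc", NA_character_)),
    rev_qc = as.character(g("revQc", NA_character_)),
    provenance = as.character(g("provenance", NA_character_)),
    consensus_length = as.integer(g("consensusLength", NA_integer_)),
    length_category = as.character(g("lengthCategory", NA_character_)),
    overlap_length = as.integer(g("overlapLength", NA_integer_)),
    n_disagreements = as.integer(g("nDisagreements", NA_integer_)),
    top_accession = as.character(v("topAccession")),
    top_genus = as.character(v("topGenus")),
    top_species = as.character(v("topSpecies")),
    aligned_length = as.numeric(v("alignedLength")),
    query_cover = as.numeric(v("queryCover")),
    percent_identity = as.numeric(v("percentIdentity")),
    distance_next_species = as.numeric(v("distanceNextSpecies")),
    db_tier = as.character(v("dbTier")),
    category = category(result),
    reported_name = reportedName(result),
    comment = result@comment,
    qc_reasons = paste(qcReasons(result), collapse = "; "),
    stringsAsFactors = FALSE)
}

#' Concordance with a reference identification
#'
#' A result is concordant when it identifies the organism correctly to at
#' least the genus level (a species-level match is not required);
#' inconclusive or excluded results are omitted from agreement
#' calculations rather than counted discordant.  References above genus
#' rank (e.g. a family name) are compared literally at their stated rank.
#'
#' @param result An \linkS4class{IdentificationResult}.
#' @param referenceId Reference identification, e.g. "Fusobacterium
#'   necrophorum", "Parvimonas sp.", or a family name.
#' @return One of \code{"concordant"}, \code{"discordant"},
#'   \code{"omitted"}.
#' @export
concordance <- function(result, referenceId) {
  stopifnot(is(result, "IdentificationResult"))
  referenceId <- trimws(as.character(referenceId)[1L])
  if (is.na(referenceId) || !nzchar(referenceId) ||
      !grepl("^[A-Za-z]", referenceId))
    stop("unparseable reference identification: ", referenceId)
  if (category(result) %in% c("inconclusive", "excluded"))
    return("omitted")
  refGenus <- strsplit(referenceId, "\\s+")[[1L]][1L]
  resGenus <- metrics(result)$topGenus
  if (!is.null(resGenus) && !is.na(resGenus) &&
      identical(resGenus, refGenus))
    "concordant"
  else "discordant"
}
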