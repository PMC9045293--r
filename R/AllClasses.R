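#' @import methods
NULL

#' SangerRead: one direction of a Sanger chromatogram
#'
#' Holds the basecalls, per-base Phred quality values and (optionally) the
#' processed trace channels and peak locations for a single sequencing read.
#'
#' @slot sampleId Sample identifier.
#' @slot direction Either \code{"forward"} or \code{"reverse"}.
#' @slot bases Basecall string over the IUPAC DNA alphabet.
#' @slot qualities Integer Phred quality value (0--62) per base.
#' @slot peakLocations Optional integer trace index per base, strictly
#'   increasing; length 0 when absent.
#' @slot traces Optional integer matrix of processed trace signal, one column
#'   per channel named \code{A,C,G,T}; 0 rows when absent.
#' @slot sourcePath Path of the file the read was parsed from, or \code{NA}.
#' @export
setClass("SangerRead",
  representation(
    sampleId      = "character",
    direction     = "character",
    bases         = "character",
    qualities     = "integer",
    peakLocations = "integer",
    traces        = "matrix",
    sourcePath    = "character"
  ),
  prototype(
    sampleId = "sample", direction = "forward", bases = "",
    qualities = integer(0), peakLocations = integer(0),
    traces = matrix(integer(0), nrow = 0, ncol = 4,
                    dimnames = list(NULL, c("A", "C", "G", "T"))),
    sourcePath = NA_character_
  )
)

setValidity("SangerRead", function(object) {
  msg <- character(0)
  n <- nchar(object@bases)
  if (!object@direction %in% c("forward", "reverse"))
    msg <- c(msg, "direction must be 'forward' or 'reverse'")
  if (!.isIUPAC(object@bases))
    msg <- c(msg, "bases contain non-IUPAC characters")
  if (length(object@qualities) != n)
    msg <- c(msg, "length(qualities) must equal number of bases")
  if (length(object@qualities) &&
      (anyNA(object@qualities) ||
       any(object@qualities < 0L) || any(object@qualities > 62L)))
    msg <- c(msg, "quality values must lie in [0, 62]")
  if (length(object@peakLocations)) {
    if (length(object@peakLocations) != n)
      msg <- c(msg, "peakLocations must have one entry per base")
    else if (any(diff(object@peakLocations) <= 0L))
      msg <- c(msg, "peakLocations must be strictly increasing")
  }
  if (nrow(object@traces)) {
    if (ncol(object@traces) != 4L)
      msg <- c(msg, "traces must have 4 channels (A,C,G,T)")
    if (any(object@traces < 0L))
      msg <- c(msg, "trace values must be non-negative")
    if (length(object@peakLocations) &&
        max(object@peakLocations) > nrow(object@traces))
      msg <- c(msg, "peakLocations exceed trace length")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SangerRead
#'
#' @param sampleId Sample identifier.
#' @param direction \code{"forward"} or \code{"reverse"}.
#' @param bases Basecall string (IUPAC alphabet, uppercase).
#' @param qualities Integer vector of Phred QVs, one per base.
#' @param peakLocations Optional strictly increasing integer vector of trace
#'   indices, one per base.
#' @param traces Optional integer matrix (columns A,C,G,T) of trace signal.
#' @param sourcePath Optional provenance path.
#' @return A \linkS4class{SangerRead}.
#' @examples
#' SangerRead("s1", "forward", "ACGT", c(40L, 40L, 40L, 40L))
#' @export
SangerRead <- function(sampleId, direction, bases, qualities,
                       peakLocations = integer(0), traces = NULL,
                       sourcePath = NA_character_) {
  if (is.null(traces))
    traces <- matrix(integer(0), nrow = 0, ncol = 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
  storage.mode(traces) <- "integer"
  new("SangerRead", sampleId = as.character(sampleId),
      direction = as.character(direction), bases = toupper(bases),
      qualities = as.integer(qualities),
      peakLocations = as.integer(peakLocations),
      traces = traces, sourcePath = as.character(sourcePath))
}

#' TrimWindow: retained index range after quality trimming
#'
#' @slot start First retained base (1-based, inclusive).
#' @slot end Last retained base (1-based, inclusive); \code{end < start}
#'   (canonically \code{start = 1, end = 0}) denotes an empty window.
#' @slot passed Whether the window satisfies the minimum clear length.
#' @slot reason Human-readable explanation when \code{passed} is FALSE.
#' @slot meanQV Mean Phred quality over the retained window (NaN if empty).
#' @slot nAmbiguous Count of non-ACGT bases in the window.
#' @export
setClass("TrimWindow",
  representation(start = "integer", end = "integer", passed = "logical",
                 reason = "character", meanQV = "numeric",
                 nAmbiguous = "integer"),
  prototype(start = 1L, end = 0L, passed = FALSE, reason = "",
            meanQV = NaN, nAmbiguous = 0L)
)

setValidity("TrimWindow", function(object) {
  if (object@end >= object@start && object@start < 1L)
    return("non-empty window must have start >= 1")
  TRUE
})

#' ConsensusRecord: merged (or single-read) query sequence
#'
#' @slot sampleId Sample identifier.
#' @slot sequence Consensus DNA string (IUPAC).
#' @slot qualities Per-base Phred QV.
#' @slot provenance One of \code{"consensus"}, \code{"single_forward"},
#'   \code{"single_reverse"}.
#' @slot overlapLength Aligned overlap columns between the two reads (0 for
#'   single-read records).
#' @slot nDisagreements Conflicting forward/reverse columns in the overlap.
#' @slot lengthCategory \code{"long"} (>440 bp), \code{"medium"}
#'   (400--440 bp) or \code{"short"} (<400 bp).
#' @export
setClass("ConsensusRecord",
  representation(sampleId = "character", sequence = "character",
                 qualities = "integer", provenance = "character",
                 overlapLength = "integer", nDisagreements = "integer",
                 lengthCategory = "character")
)

setValidity("ConsensusRecord", function(object) {
  msg <- character(0)
  n <- nchar(object@sequence)
  if (length(object@qualities) != n)
    msg <- c(msg, "length(qualities) must equal sequence length")
  if (!object@provenance %in% c("consensus", "single_forward",
                                "single_reverse"))
    msg <- c(msg, "invalid provenance")
  if (object@provenance == "consensus" && object@overlapLength < 1L)
    msg <- c(msg, "consensus provenance requires overlapLength >= 1")
  expect <- if (n > 440L) "long" else if (n >= 400L) "medium" else "short"
  if (object@lengthCategory != expect)
    msg <- c(msg, sprintf("lengthCategory '%s' inconsistent with length %d",
                          object@lengthCategory, n))
  if (length(msg)) msg else TRUE
})

#' Construct a ConsensusRecord
#'
#' The length category is derived from the sequence length:
#' >440 bp is \code{"long"}, 400--440 bp inclusive is \code{"medium"},
#' <400 bp is \code{"short"} (excluded from database search).
#'
#' @param sampleId Sample identifier.
#' @param sequence Consensus sequence (IUPAC, uppercase).
#' @param qualities Integer Phred QVs, one per base.
#' @param provenance \code{"consensus"}, \code{"single_forward"} or
#'   \code{"single_reverse"}.
#' @param overlapLength,nDisagreements Overlap statistics from the merge
#'   (0 for single-read records).
#' @return A \linkS4class{ConsensusRecord}.
#' @export
ConsensusRecord <- function(sampleId, sequence, qualities, provenance,
                            overlapLength = 0L, nDisagreements = 0L) {
  n <- nchar(sequence)
  cat <- if (n > 440L) "long" else if (n >= 400L) "medium" else "short"
  new("ConsensusRecord", sampleId = as.character(sampleId),
      sequence = toupper(sequence), qualities = as.integer(qualities),
      provenance = provenance, overlapLength = as.integer(overlapLength),
      nDisagreements = as.integer(nDisagreements), lengthCategory = cat)
}

#' ReferenceDB: local 16S reference sequences with taxonomy
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet} named by accession.
#' @slot taxonomy data.frame with columns \code{accession}, \code{genus},
#'   \code{species} and optional \code{group} (species-group label such as
#'   "mitis group"; \code{NA} when absent).
#' @slot tier \code{"primary_16S"} or \code{"fallback_broad"}.
#' @export
setClass("ReferenceDB",
  representation(sequences = "DNAStringSet", taxonomy = "data.frame",
                 tier = "character")
)

setValidity("ReferenceDB", function(object) {
  msg <- character(0)
  tax <- object@taxonomy
  need <- c("accession", "genus", "species", "group")
  if (!all(need %in% names(tax)))
    msg <- c(msg, "taxonomy must have columns accession, genus, species, group")
  else if (!all(names(object@sequences) %in% tax$accession))
    msg <- c(msg, "every sequence accession needs a taxonomy entry")
  if (length(object@sequences) &&
      any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "reference sequences must be non-empty")
  if (!object@tier %in% c("primary_16S", "fallback_broad"))
    msg <- c(msg, "tier must be 'primary_16S' or 'fallback_broad'")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceDB
#'
#' @param sequences Named character vector or \code{DNAStringSet} of
#'   reference sequences (names are accessions).
#' @param taxonomy data.frame mapping \code{accession} to \code{genus},
#'   \code{species} and optional \code{group} label.
#' @param tier Database tier, \code{"primary_16S"} (default) or
#'   \code{"fallback_broad"}.
#' @return A \linkS4class{ReferenceDB}.
#' @export
ReferenceDB <- function(sequences, taxonomy, tier = "primary_16S") {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  if (is.null(taxonomy$group)) taxonomy$group <- NA_character_
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  new("ReferenceDB", sequences = sequences, taxonomy = taxonomy, tier = tier)
}

#' HitTable: ranked reference-search hits for one query
#'
#' The \code{hits} slot is a data.frame sorted by \code{score} (desc), then
#' \code{percentIdentity} (desc), then \code{accession} (asc), with columns
#' \code{accession, genus, species, group, alignedLength, percentIdentity,
#' queryCover, score}.
#'
#' @slot queryId Query (sample) identifier.
#' @slot hits The ranked hit data.frame.
#' @slot dbTier Tier of the database the hits came from.
#' @export
setClass("HitTable",
  representation(queryId = "character", hits = "data.frame",
                 dbTier = "character")
)

setValidity("HitTable", function(object) {
  h <- object@hits
  need <- c("accession", "genus", "species", "group", "alignedLength",
            "percentIdentity", "queryCover", "score")
  if (!all(need %in% names(h)))
    return(paste("hits must have columns:", paste(need, collapse = ", ")))
  if (nrow(h)) {
    if (any(h$percentIdentity < 0 | h$percentIdentity > 100))
      return("percentIdentity out of [0, 100]")
    if (any(h$queryCover < 0 | h$queryCover > 100))
      return("queryCover out of [0, 100]")
    if (any(h$alignedLength < 1L))
      return("alignedLength must be >= 1")
  }
  TRUE
})

.emptyHits <- function() {
  data.frame(accession = character(0), genus = character(0),
             species = character(0), group = character(0),
             alignedLength = integer(0), percentIdentity = numeric(0),
             queryCover = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

.sortHits <- function(h) {
  if (!nrow(h)) return(h)
  h <- h[order(-h$score, -h$percentIdentity, h$accession), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Construct a HitTable
#'
#' @param queryId Query identifier.
#' @param hits Hit data.frame (will be sorted deterministically).
#' @param dbTier Database tier label.
#' @return A \linkS4class{HitTable}.
#' @export
HitTable <- function(queryId, hits = .emptyHits(), dbTier = "primary_16S") {
  if (is.null(hits$group)) hits$group <- rep(NA_character_, nrow(hits))
  new("HitTable", queryId = as.character(queryId),
      hits = .sortHits(hits), dbTier = dbTier)
}

#' IdentificationResult: the final call for one sample
#'
#' @slot category \code{"species"}, \code{"genus"}, \code{"inconclusive"} or
#'   \code{"excluded"}.
#' @slot reportedName Reported organism name ("Genus species", "Genus sp.",
#'   a species-group label, or "Inconclusive").
#' @slot comment Optional reviewer comment ("most closely related to ...")
#'   attached to genus-level calls.
#' @slot qcReasons Criteria that failed or capped the call.
#' @slot metrics Named list of the decision metrics (see
#'   \code{\link{idMetrics}}).
#' @export
setClass("IdentificationResult",
  representation(category = "character", reportedName = "character",
                 comment = "character", qcReasons = "character",
                 metrics = "list")
)

setValidity("IdentificationResult", function(object) {
  msg <- character(0)
  if (!object@category %in% c("species", "genus", "inconclusive", "excluded"))
    msg <- c(msg, "invalid category")
  if (object@category == "species") {
    sp <- object@metrics$topSpecies
    if (is.null(sp) || is.na(sp) ||
        !grepl(sp, object@reportedName, fixed = TRUE))
      msg <- c(msg, "species-level call must report the species epithet")
  }
  if (object@category == "inconclusive" && !length(object@qcReasons))
    msg <- c(msg, "inconclusive result requires at least one QC reason")
  if (length(msg)) msg else TRUE
})
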