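# Bidirectional consensus: merge a trimmed forward read with the reverse
# complement of a trimmed reverse read over a free-end-gap alignment.

#' Merge trimmed forward and reverse reads into a consensus
#'
#' The reverse read is reverse-complemented and aligned to the forward read
#' with a semiglobal (free end gaps) alignment.  Per aligned column:
#' agreeing bases are kept with the larger of the two QVs; disagreeing
#' bases take the higher-QV base when the QV difference is at least
#' \code{qvGap}, otherwise the IUPAC ambiguity code of the pair with the
#' smaller QV.  Columns covered by only one read take that read's base.
#' Flanks outside the aligned region are taken from whichever read extends
#' further.
#'
#' @param fwd Trimmed forward \linkS4class{SangerRead} (as stored, 5'->3').
#' @param rev Trimmed reverse \linkS4class{SangerRead} (basecalls as read
#'   off the instrument; reverse-complemented internally).
#' @param qvGap QV difference at or above which a conflict is resolved to
#'   the higher-QV base (default 10).
#' @param minOverlap Minimum aligned overlap columns to accept the contig
#'   (default 20).
#' @param minOverlapIdentity Minimum identity over the overlap (default
#'   0.80).
#' @param scoring \code{\link{alignScoring}} parameters for the overlap
#'   alignment.
#' @return A \linkS4class{ConsensusRecord} with provenance
#'   \code{"consensus"}.
#' @section Errors: If no alignment with at least \code{minOverlap} columns
#'   at \code{minOverlapIdentity} identity exists, the reads do not form a
#'   contig and an error is raised; callers typically fall back to the best
#'   single read.
#' @export
mergeReads <- function(fwd, rev, qvGap = 10L, minOverlap = 20L,
                       minOverlapIdentity = 0.80,
                       scoring = alignScoring()) {
  stopifnot(is(fwd, "SangerRead"), is(rev, "SangerRead"))
  fSeq <- bases(fwd); fQ <- qualities(fwd)
  rSeq <- revComp(bases(rev)); rQ <- rev(qualities(rev))
  if (!nchar(fSeq) || !nchar(rSeq))
    stop("reads do not form a contig: empty trimmed read")

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(fSeq), Biostrings::DNAString(rSeq),
    type = "overlap", substitutionMatrix = .substMatrix(scoring$match,
                                                        scoring$mismatch),
    gapOpening = scoring$gapOpening, gapExtension = scoring$gapExtension)

  ap <- .splitBases(as.character(Biostrings::pattern(aln)))
  as_ <- .splitBases(as.character(Biostrings::subject(aln)))
  cols <- length(ap)
  matches <- sum(ap == as_ & ap != "-")
  if (cols < minOverlap || matches / max(cols, 1L) < minOverlapIdentity)
    stop(sprintf(
      "reads do not form a contig (overlap %d columns, identity %.1f%%)",
      cols, 100 * matches / max(cols, 1L)))

  ps <- Biostrings::start(Biostrings::pattern(aln))
  pe <- Biostrings::end(Biostrings::pattern(aln))
  ss <- Biostrings::start(Biostrings::subject(aln))
  se <- Biostrings::end(Biostrings::subject(aln))

  # merged overlap
  outB <- character(0); outQ <- integer(0)
  i <- ps; j <- ss; nDis <- 0L
  for (k in seq_len(cols)) {
    cp <- ap[k]; cs <- as_[k]
    if (cp == "-") {
      outB <- c(outB, cs); outQ <- c(outQ, rQ[j]); j <- j + 1L
    } else if (cs == "-") {
      outB <- c(outB, cp); outQ <- c(outQ, fQ[i]); i <- i + 1L
    } else {
      if (cp == cs) {
        outB <- c(outB, cp); outQ <- c(outQ, max(fQ[i], rQ[j]))
      } else {
        nDis <- nDis + 1L
        if (abs(fQ[i] - rQ[j]) >= qvGap) {
          if (fQ[i] > rQ[j]) { outB <- c(outB, cp); outQ <- c(outQ, fQ[i]) }
          else               { outB <- c(outB, cs); outQ <- c(outQ, rQ[j]) }
        } else {
          outB <- c(outB, .ambiguityCode(cp, cs))
          outQ <- c(outQ, min(fQ[i], rQ[j]))
        }
      }
      i <- i + 1L; j <- j + 1L
    }
  }

  # flanks: whichever read extends further on each side
  leftB <- character(0); leftQ <- integer(0)
  if (ps - 1L >= ss - 1L && ps > 1L) {
    leftB <- .splitBases(substr(fSeq, 1L, ps - 1L)); leftQ <- fQ[seq_len(ps - 1L)]
  } else if (ss > 1L) {
    leftB <- .splitBases(substr(rSeq, 1L, ss - 1L)); leftQ <- rQ[seq_len(ss - 1L)]
  }
  fTail <- nchar(fSeq) - pe; rTail <- nchar(rSeq) - se
  rightB <- character(0); rightQ <- integer(0)
  if (fTail >= rTail && fTail > 0L) {
    rightB <- .splitBases(substr(fSeq, pe + 1L, nchar(fSeq)))
    rightQ <- fQ[(pe + 1L):nchar(fSeq)]
  } else if (rTail > 0L) {
    rightB <- .splitBases(substr(rSeq, se + 1L, nchar(rSeq)))
    rightQ <- rQ[(se + 1L):nchar(rSeq)]
  }

  ConsensusRecord(sampleId(fwd),
                  paste(c(leftB, outB, rightB), collapse = ""),
                  c(leftQ, outQ, rightQ),
                  provenance = "consensus",
                  overlapLength = cols, nDisagreements = nDis)
}

#' Wrap a single trimmed read as the query record
#'
#' Used when only one direction passed QC: reverse reads are
#' reverse-complemented so the query is always in forward orientation.
#'
#' @param read A trimmed \linkS4class{SangerRead}.
#' @return A \linkS4class{ConsensusRecord} with provenance
#'   \code{"single_forward"} or \code{"single_reverse"}.
#' @export
singleReadRecord <- function(read) {
  stopifnot(is(read, "SangerRead"))
  if (direction(read) == "reverse")
    ConsensusRecord(sampleId(read), revComp(bases(read)),
                    rev(qualities(read)), provenance = "single_reverse")
  else
    ConsensusRecord(sampleId(read), bases(read), qualities(read),
                    provenance = "single_forward")
}

#' Sequence-length QC category
#'
#' Consensus (or single-read) queries are binned by length: \code{"long"}
#' (>440 bp), \code{"medium"} (400--440 bp inclusive) and \code{"short"}
#' (<400 bp).  Short queries are excluded from the database search;
#' medium queries can be identified at most to genus level.
#'
#' @param record A \linkS4class{ConsensusRecord}.
#' @return The category string.
#' @export
assignLengthCategory <- function(record) {
  stopifnot(is(record, "ConsensusRecord"))
  lengthCategory(record)
}
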