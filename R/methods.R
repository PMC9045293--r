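# Accessors and show methods.

#' @rdname SangerRead-class
#' @export
setMethod("sampleId", "SangerRead", function(x) x@sampleId)
#' @rdname SangerRead-class
#' @export
setMethod("direction", "SangerRead", function(x) x@direction)
#' @rdname SangerRead-class
#' @export
setMethod("bases", "SangerRead", function(x) x@bases)
#' @rdname SangerRead-class
#' @export
setMethod("qualities", "SangerRead", function(x) x@qualities)
#' @rdname SangerRead-class
#' @export
setMethod("peakLocations", "SangerRead", function(x) x@peakLocations)
#' @rdname SangerRead-class
#' @export
setMethod("traces", "SangerRead", function(x) x@traces)
#' @rdname SangerRead-class
#' @export
setMethod("length", "SangerRead", function(x) nchar(x@bases))

setMethod("show", "SangerRead", function(object) {
  n <- nchar(object@bases)
  cat(sprintf("SangerRead '%s' (%s), %d bases\n",
              object@sampleId, object@direction, n))
  if (n) {
    head <- substr(object@bases, 1L, min(n, 40L))
    cat(sprintf("  bases:  %s%s\n", head, if (n > 40L) "..." else ""))
    cat(sprintf("  mean QV: %.1f  traces: %s  peaks: %s\n",
                mean(object@qualities),
                if (nrow(object@traces)) "yes" else "no",
                if (length(object@peakLocations)) "yes" else "no"))
  }
})

#' @rdname TrimWindow-class
#' @param x,object A \linkS4class{TrimWindow}.
#' @export
setMethod("length", "TrimWindow", function(x) max(0L, x@end - x@start + 1L))

setMethod("show", "TrimWindow", function(object) {
  if (object@end >= object@start)
    cat(sprintf("TrimWindow [%d, %d] (%d bases), mean QV %.1f, %s\n",
                object@start, object@end, object@end - object@start + 1L,
                object@meanQV,
                if (object@passed) "passed" else
                  paste0("failed: ", object@reason)))
  else
    cat(sprintf("TrimWindow (empty), failed: %s\n", object@reason))
})

#' @rdname ConsensusRecord-class
#' @param x,object A \linkS4class{ConsensusRecord}.
#' @export
setMethod("sampleId", "ConsensusRecord", function(x) x@sampleId)
#' @rdname ConsensusRecord-class
#' @export
setMethod("consensusSequence", "ConsensusRecord", function(x) x@sequence)
#' @rdname ConsensusRecord-class
#' @export
setMethod("qualities", "ConsensusRecord", function(x) x@qualities)
#' @rdname ConsensusRecord-class
#' @export
setMethod("provenance", "ConsensusRecord", function(x) x@provenance)
#' @rdname ConsensusRecord-class
#' @export
setMethod("lengthCategory", "ConsensusRecord", function(x) x@lengthCategory)
#' @rdname ConsensusRecord-class
#' @export
setMethod("length", "ConsensusRecord", function(x) nchar(x@sequence))

setMethod("show", "ConsensusRecord", function(object) {
  cat(sprintf(
    "ConsensusRecord '%s': %d bp (%s), %s, overlap %d, disagreements %d\n",
    object@sampleId, nchar(object@sequence), object@lengthCategory,
    object@provenance, object@overlapLength, object@nDisagreements))
})

#' @rdname ReferenceDB-class
#' @param x,object A \linkS4class{ReferenceDB}.
#' @export
setMethod("taxonomy", "ReferenceDB", function(x) x@taxonomy)
#' @rdname ReferenceDB-class
#' @export
setMethod("length", "ReferenceDB", function(x) length(x@sequences))
#' @rdname ReferenceDB-class
#' @export
setMethod("dbTier", "ReferenceDB", function(x) x@tier)

setMethod("show", "ReferenceDB", function(object) {
  cat(sprintf("ReferenceDB (%s): %d sequences, %d genera\n",
              object@tier, length(object@sequences),
              length(unique(object@taxonomy$genus))))
})

#' @rdname HitTable-class
#' @param x,object A \linkS4class{HitTable}.
#' @export
setMethod("hits", "HitTable", function(x) x@hits)
#' @rdname HitTable-class
#' @export
setMethod("dbTier", "HitTable", function(x) x@dbTier)
#' @rdname HitTable-class
#' @export
setMethod("sampleId", "HitTable", function(x) x@queryId)
#' @rdname HitTable-class
#' @export
setMethod("length", "HitTable", function(x) nrow(x@hits))

setMethod("show", "HitTable", function(object) {
  cat(sprintf("HitTable for '%s' (%s): %d hits\n",
              object@queryId, object@dbTier, nrow(object@hits)))
  if (nrow(object@hits))
    print(utils::head(object@hits, 5L))
})

#' @rdname IdentificationResult-class
#' @param x,object An \linkS4class{IdentificationResult}.
#' @export
setMethod("category", "IdentificationResult", function(x) x@category)
#' @rdname IdentificationResult-class
#' @export
setMethod("reportedName", "IdentificationResult", function(x) x@reportedName)
#' @rdname IdentificationResult-class
#' @export
setMethod("qcReasons", "IdentificationResult", function(x) x@qcReasons)
#' @rdname IdentificationResult-class
#' @export
setMethod("metrics", "IdentificationResult", function(x) x@metrics)

setMethod("show", "IdentificationResult", function(object) {
  cat(sprintf("Identification: %s (%s)\n",
              object@reportedName, object@category))
  if (nzchar(object@comment)) cat("  comment:", object@comment, "\n")
  if (length(object@qcReasons))
    cat("  QC:", paste(object@qcReasons, collapse = "; "), "\n")
})
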