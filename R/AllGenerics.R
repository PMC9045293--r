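#' @rdname SangerRead-class
#' @param object,x A package object.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname SangerRead-class
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @rdname SangerRead-class
#' @export
setGeneric("bases", function(x) standardGeneric("bases"))

#' @rdname SangerRead-class
#' @export
setGeneric("qualities", function(x) standardGeneric("qualities"))

#' @rdname SangerRead-class
#' @export
setGeneric("peakLocations", function(x) standardGeneric("peakLocations"))

#' @rdname SangerRead-class
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname ConsensusRecord-class
#' @export
setGeneric("consensusSequence", function(x) standardGeneric("consensusSequence"))

#' @rdname ConsensusRecord-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ConsensusRecord-class
#' @export
setGeneric("lengthCategory", function(x) standardGeneric("lengthCategory"))

#' @rdname HitTable-class
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname HitTable-class
#' @export
setGeneric("dbTier", function(x) standardGeneric("dbTier"))

#' @rdname IdentificationResult-class
#' @export
setGeneric("category", function(x) standardGeneric("category"))

#' @rdname IdentificationResult-class
#' @export
setGeneric("reportedName", function(x) standardGeneric("reportedName"))

#' @rdname IdentificationResult-class
#' @export
setGeneric("qcReasons", function(x) standardGeneric("qcReasons"))

#' @rdname IdentificationResult-class
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname ReferenceDB-class
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))
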