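## Accessor generics and methods; user code never reaches into slots.

#' @rdname accessors
#' @param object an ervclock S4 object.
#' @export
setGeneric("distValue", function(object) standardGeneric("distValue"))
#' @rdname accessors
#' @export
setGeneric("distSE", function(object) standardGeneric("distSE"))
#' @rdname accessors
#' @export
setGeneric("divergence", function(object) standardGeneric("divergence"))
#' @rdname accessors
#' @export
setGeneric("ages", function(object) standardGeneric("ages"))
#' @rdname accessors
#' @export
setGeneric("intactness", function(object) standardGeneric("intactness"))
#' @rdname accessors
#' @export
setGeneric("ltrPair", function(object) standardGeneric("ltrPair"))
#' @rdname accessors
#' @export
setGeneric("internalRange", function(object) standardGeneric("internalRange"))
#' @rdname accessors
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("keptColumns", function(object) standardGeneric("keptColumns"))
#' @rdname accessors
#' @export
setGeneric("trueAge", function(object) standardGeneric("trueAge"))
#' @rdname accessors
#' @export
setGeneric("expectedDivergence", function(object) standardGeneric("expectedDivergence"))
#' @rdname accessors
#' @export
setGeneric("contigSeq", function(object) standardGeneric("contigSeq"))
#' @rdname accessors
#' @export
setGeneric("defectEvents", function(object) standardGeneric("defectEvents"))
#' @rdname accessors
#' @export
setGeneric("polReference", function(object) standardGeneric("polReference"))
#' @rdname accessors
#' @export
setGeneric("siteCounts", function(object) standardGeneric("siteCounts"))

#' Accessors for ervclock value objects
#'
#' Small read-only accessors: \code{distValue}/\code{distSE} return the point
#' estimate and standard error of a \linkS4class{DistanceEstimate} (or the
#' value matrix of a \linkS4class{DistanceMatrix}); \code{divergence},
#' \code{ages}, \code{intactness}, \code{ltrPair} and \code{internalRange}
#' unpack a \linkS4class{ProvirusCall}; \code{membership} returns the named
#' lineage vector of a \linkS4class{LineagePartition}; \code{keptColumns} the
#' kept column intervals of a \linkS4class{TrimmedAlignment}; the remaining
#' accessors expose \linkS4class{SimulatedProvirus} ground truth.
#'
#' @name accessors
#' @return the slot value named by the accessor.
NULL

#' @rdname accessors
setMethod("distValue", "DistanceEstimate", function(object) object@value)
#' @rdname accessors
setMethod("distValue", "DistanceMatrix", function(object) {
  m <- object@values
  dimnames(m) <- list(object@labels, object@labels)
  m
})
#' @rdname accessors
setMethod("distSE", "DistanceEstimate", function(object) object@se)
#' @rdname accessors
setMethod("distSE", "DistanceMatrix", function(object) {
  m <- object@se
  dimnames(m) <- list(object@labels, object@labels)
  m
})
#' @rdname accessors
setMethod("siteCounts", "SiteCounts", function(object)
  c(n = object@n, ts = object@ts, tv = object@tv))

#' @rdname accessors
setMethod("divergence", "ProvirusCall", function(object) object@divergence)
#' @rdname accessors
setMethod("ages", "ProvirusCall", function(object) object@ages)
#' @rdname accessors
setMethod("intactness", "ProvirusCall", function(object) object@intactness)
#' @rdname accessors
setMethod("ltrPair", "ProvirusCall", function(object) object@ltrPair)
#' @rdname accessors
setMethod("internalRange", "ProvirusCall", function(object) object@internal)

#' @rdname accessors
setMethod("membership", "LineagePartition", function(object) object@membership)
#' @rdname accessors
setMethod("keptColumns", "TrimmedAlignment", function(object) object@keptColumns)

#' @rdname accessors
setMethod("trueAge", "SimulatedProvirus", function(object) object@trueAge)
#' @rdname accessors
setMethod("expectedDivergence", "SimulatedProvirus", function(object)
  object@expectedDivergence)
#' @rdname accessors
setMethod("contigSeq", "SimulatedProvirus", function(object) object@contig)
#' @rdname accessors
setMethod("defectEvents", "SimulatedProvirus", function(object) object@defects)
#' @rdname accessors
setMethod("defectEvents", "ORFIntactnessReport", function(object) object@events)
#' @rdname accessors
setMethod("polReference", "SimulatedProvirus", function(object) object@polReference)
#' @rdname accessors
setMethod("ltrPair", "SimulatedProvirus", function(object)
  list(ltr5 = object@ltr5, ltr3 = object@ltr3, tsd = object@tsd))
#' @rdname accessors
setMethod("internalRange", "SimulatedProvirus", function(object) object@internal)
#' @rdname accessors
setMethod("intactness", "ORFIntactnessReport", function(object)
  c(nonsense = object@nNonsense, frameshift = object@nFrameshift))
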