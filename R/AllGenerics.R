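#' Accessors for slideFRET data objects
#'
#' \code{traceData} returns the underlying per-record data.frame of a
#' \linkS4class{TraceSet}, \linkS4class{AlexSeries},
#' \linkS4class{FretTraceSet}, \linkS4class{EventTable} or
#' \linkS4class{TimelineSet}; \code{traceManifest} the acquisition
#' \linkS4class{Manifest}; \code{molecules} the molecule identifiers;
#' \code{nMolecules} their count; \code{droppedBlocks} the per-molecule count
#' of unpaired trailing excitation blocks of an \linkS4class{AlexSeries}.
#'
#' @param x a slideFRET data object.
#' @return See the description for each accessor.
#' @name accessors
#' @aliases traceData traceManifest molecules nMolecules droppedBlocks
NULL

#' @rdname accessors
#' @export
setGeneric("traceData", function(x) standardGeneric("traceData"))

#' @rdname accessors
#' @export
setGeneric("traceManifest", function(x) standardGeneric("traceManifest"))

#' @rdname accessors
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname accessors
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' @rdname accessors
#' @export
setGeneric("droppedBlocks", function(x) standardGeneric("droppedBlocks"))

#' @rdname accessors
setMethod("traceData", "TraceSet", function(x) x@data)
#' @rdname accessors
setMethod("traceData", "AlexSeries", function(x) x@data)
#' @rdname accessors
setMethod("traceData", "FretTraceSet", function(x) x@data)
#' @rdname accessors
setMethod("traceData", "EventTable", function(x) x@data)
#' @rdname accessors
setMethod("traceData", "TimelineSet", function(x) x@data)

#' @rdname accessors
setMethod("traceManifest", "TraceSet", function(x) x@manifest)
#' @rdname accessors
setMethod("traceManifest", "AlexSeries", function(x) x@manifest)
#' @rdname accessors
setMethod("traceManifest", "FretTraceSet", function(x) x@manifest)

#' @rdname accessors
setMethod("molecules", "TraceSet", function(x) unique(x@data$molecule_id))
#' @rdname accessors
setMethod("molecules", "AlexSeries", function(x) unique(x@data$molecule_id))
#' @rdname accessors
setMethod("molecules", "FretTraceSet", function(x) unique(x@data$molecule_id))
#' @rdname accessors
setMethod("molecules", "EventTable", function(x) x@data$molecule_id)
#' @rdname accessors
setMethod("molecules", "TimelineSet", function(x) x@data$molecule_id)

#' @rdname accessors
setMethod("nMolecules", "TraceSet", function(x) length(molecules(x)))
#' @rdname accessors
setMethod("nMolecules", "AlexSeries", function(x) length(molecules(x)))
#' @rdname accessors
setMethod("nMolecules", "FretTraceSet", function(x) length(molecules(x)))
#' @rdname accessors
setMethod("nMolecules", "EventTable", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nMolecules", "TimelineSet", function(x) nrow(x@data))

#' @rdname accessors
setMethod("droppedBlocks", "AlexSeries", function(x) x@dropped)

#' @export
#' @method as.data.frame EventTable
as.data.frame.EventTable <- function(x, ...) x@data

setMethod("as.data.frame", "EventTable", as.data.frame.EventTable)
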