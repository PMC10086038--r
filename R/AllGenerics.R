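#' Accessor generics
#'
#' Small accessor family used across the package's S4 containers.
#'
#' @param object an S4 object from this package
#' @param ... passed to methods
#' @return the requested component (see the class documentation)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("siteTable", function(object, ...) standardGeneric("siteTable"))

#' @rdname accessors
#' @export
setGeneric("channelPairs", function(object, ...) standardGeneric("channelPairs"))

#' @rdname accessors
#' @export
setGeneric("nSites", function(object, ...) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(object, ...) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(object, ...) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(object, ...) standardGeneric("epochTimes"))

#' @rdname accessors
#' @export
setGeneric("epochMeta", function(object, ...) standardGeneric("epochMeta"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(object, ...) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("evokedValues", function(object, ...) standardGeneric("evokedValues"))

#' @rdname accessors
#' @export
setGeneric("residualTraces", function(object, ...) standardGeneric("residualTraces"))

#' @rdname accessors
#' @export
setGeneric("betaTable", function(object, ...) standardGeneric("betaTable"))

#' @rdname accessors
#' @export
setGeneric("clusterTable", function(object, ...) standardGeneric("clusterTable"))

#' @rdname accessors
#' @export
setGeneric("significanceMask", function(object, ...) standardGeneric("significanceMask"))

#' @rdname accessors
#' @export
setGeneric("medianResidualTraces", function(object, ...) standardGeneric("medianResidualTraces"))
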