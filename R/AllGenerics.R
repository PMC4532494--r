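#' @rdname DomainStructure-class
#' @param object,x a \code{DomainStructure}, \code{StructuralAlignment} or
#'   \code{DissimilarityMatrix}.
#' @export
setGeneric("domainId", function(object) standardGeneric("domainId"))

#' @rdname DomainStructure-class
#' @export
setGeneric("caCoords", function(object) standardGeneric("caCoords"))

#' @rdname DomainStructure-class
#' @export
setGeneric("residueNumbers", function(object) standardGeneric("residueNumbers"))

#' @rdname DomainStructure-class
#' @export
setGeneric("domainLength", function(object) standardGeneric("domainLength"))

#' @rdname DomainStructure-class
#' @export
setGeneric("domainSequence", function(object) standardGeneric("domainSequence"))

#' @rdname StructuralAlignment-class
#' @export
setGeneric("alignedPairs", function(object) standardGeneric("alignedPairs"))

#' @rdname StructuralAlignment-class
#' @export
setGeneric("alignmentRmsd", function(object) standardGeneric("alignmentRmsd"))

#' @rdname StructuralAlignment-class
#' @export
setGeneric("nEquivalent", function(object) standardGeneric("nEquivalent"))

#' @rdname StructuralAlignment-class
#' @export
setGeneric("alignmentTransform",
           function(object) standardGeneric("alignmentTransform"))

#' @rdname StructuralAlignment-class
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
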