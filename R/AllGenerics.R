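#' Accessors for loopscreen core classes
#'
#' @param x an object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seqBases", function(x) standardGeneric("seqBases"))
#' @rdname accessors
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))
#' @rdname accessors
#' @export
setGeneric("seqKind", function(x) standardGeneric("seqKind"))
#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
#' @rdname accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))
#' @rdname accessors
#' @export
setGeneric("structureEnergy", function(x) standardGeneric("structureEnergy"))
#' @rdname accessors
#' @export
setGeneric("joinedSequence", function(x) standardGeneric("joinedSequence"))
#' @rdname accessors
#' @export
setGeneric("mirnaSpan", function(x) standardGeneric("mirnaSpan"))
#' @rdname accessors
#' @export
setGeneric("mrnaSpan", function(x) standardGeneric("mrnaSpan"))
#' @rdname accessors
#' @export
setGeneric("linkerLength", function(x) standardGeneric("linkerLength"))

#' @rdname accessors
setMethod("seqBases", "RnaSequence", function(x) x@bases)
#' @rdname accessors
setMethod("seqId", "RnaSequence", function(x) x@id)
#' @rdname accessors
setMethod("seqKind", "RnaSequence", function(x) x@kind)
#' @rdname accessors
setMethod("pairTable", "SecondaryStructure", function(x) x@pairTable)
#' @rdname accessors
setMethod("dotBracket", "SecondaryStructure", function(x) x@dotBracket)
#' @rdname accessors
setMethod("structureEnergy", "SecondaryStructure", function(x) x@energy)
#' @rdname accessors
setMethod("joinedSequence", "JoinedInteraction", function(x) x@joined)
#' @rdname accessors
setMethod("mirnaSpan", "JoinedInteraction", function(x) x@mirnaSpan)
#' @rdname accessors
setMethod("mrnaSpan", "JoinedInteraction", function(x) x@mrnaSpan)
#' @rdname accessors
setMethod("linkerLength", "JoinedInteraction", function(x) x@linkerLength)
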