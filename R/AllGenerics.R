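#' Apply a sensing operator to a signal vector
#'
#' `applyOperator` computes `A v` for a length-`nCols(op)` vector;
#' `adjointOperator` computes `A' v` for a length-`nRows(op)` vector.
#' Both are exact adjoints of one another (verified to 1e-10 in the test
#' suite), which is what iterative reconstruction requires.
#'
#' @param op a [SensingOperator-class] object.
#' @param v numeric vector of the appropriate length.
#' @return numeric vector: length `nRows(op)` for `applyOperator`,
#'   length `nCols(op)` for `adjointOperator`.
#' @export
setGeneric("applyOperator", function(op, v) standardGeneric("applyOperator"))

#' @rdname applyOperator
#' @export
setGeneric("adjointOperator", function(op, v) standardGeneric("adjointOperator"))

#' Serializable description of a sensing operator
#'
#' Returns a plain list (kind, dimensions, seed, row set, ...) from which
#' [operatorFromSpec()] rebuilds an operator with bit-identical behaviour.
#'
#' @param op a [SensingOperator-class] object.
#' @return a named list.
#' @export
setGeneric("operatorSpec", function(op) standardGeneric("operatorSpec"))

#' @rdname pixels
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname pixels
#' @export
setGeneric("dynamicRange", function(x) standardGeneric("dynamicRange"))

#' @rdname pixels
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
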