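## Accessor generics.

#' Part table of a library
#' @param x a [PartLibrary-class].
#' @return data.frame of parts, one row per part, in load order.
#' @export
setGeneric("partTable", function(x) standardGeneric("partTable"))

#' @rdname partTable
#' @export
setMethod("partTable", "PartLibrary", function(x) x@parts)

#' Number of parts in a library
#' @param x a [PartLibrary-class].
#' @export
setMethod("length", "PartLibrary", function(x) nrow(x@parts))

#' Parts of one class
#' @param x a [PartLibrary-class].
#' @param partClass one of the recognised part classes.
#' @return data.frame subset in load order.
#' @export
setGeneric("partsOfClass", function(x, partClass) standardGeneric("partsOfClass"))

#' @rdname partsOfClass
#' @export
setMethod("partsOfClass", "PartLibrary", function(x, partClass) {
  partClass <- match.arg(partClass, PART_CLASSES)
  x@parts[x@parts$part_class == partClass, , drop = FALSE]
})

#' Factors of a design space
#' @param x a [DesignSpace-class].
#' @return named list of [FactorSpec-class] objects in definition order.
#' @export
setGeneric("designFactors", function(x) standardGeneric("designFactors"))

#' @rdname designFactors
#' @export
setMethod("designFactors", "DesignSpace", function(x) {
  stats::setNames(x@factors, vapply(x@factors, function(f) f@name, character(1)))
})

#' Selected runs of a reduced design
#' @param x a [ReducedDesign-class].
#' @return data.frame of selected configurations.
#' @export
setGeneric("designRuns", function(x) standardGeneric("designRuns"))

#' @rdname designRuns
#' @export
setMethod("designRuns", "ReducedDesign", function(x) x@runs)

#' Run indices of a reduced design
#' @param x a [ReducedDesign-class].
#' @return integer vector of 0-based config_index values.
#' @export
setGeneric("runIndices", function(x) standardGeneric("runIndices"))

#' @rdname runIndices
#' @export
setMethod("runIndices", "ReducedDesign", function(x) x@runIndices)

#' Log determinant of the information matrix
#' @param x a [ReducedDesign-class].
#' @export
setGeneric("logDet", function(x) standardGeneric("logDet"))

#' @rdname logDet
#' @export
setMethod("logDet", "ReducedDesign", function(x) x@logDet)

#' D-efficiency of a design
#'
#' For a coded model matrix X with p columns and n rows,
#' `100 * det(X'X)^(1/p) / n`; equals 100 for an orthogonal two-level design
#' and lies in (0, 100] for any nonsingular design coded in \[-1, 1\].
#'
#' @param x a [ReducedDesign-class] (returns the stored value) or a numeric
#'   model matrix (computes it).
#' @return D-efficiency in percent.
#' @export
setGeneric("dEfficiency", function(x) standardGeneric("dEfficiency"))

#' @rdname dEfficiency
#' @export
setMethod("dEfficiency", "ReducedDesign", function(x) x@dEfficiency)

#' @rdname dEfficiency
#' @export
setMethod("dEfficiency", "matrix", function(x) {
  dEfficiencyFromMatrix(x)
})

#' Transfers of a picklist
#' @param x a [Picklist-class].
#' @return data.frame of transfers in execution order.
#' @export
setGeneric("transfers", function(x) standardGeneric("transfers"))

#' @rdname transfers
#' @export
setMethod("transfers", "Picklist", function(x) x@transfers)

#' Coefficients of an effect fit
#' @param object an [EffectFit-class].
#' @param ... ignored.
#' @return named numeric vector of coded-unit coefficients.
#' @export
setMethod("coef", "EffectFit", function(object, ...) object@coefficients)
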