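#' Extract the Me value from an estimate
#'
#' @param object a [MeEstimate-class] (or plain numeric, returned as is).
#' @return the effective number of chromosome segments as a number.
#' @export
setGeneric("meValue", function(object) standardGeneric("meValue"))

#' @rdname meValue
#' @export
setMethod("meValue", "MeEstimate", function(object) object@value)

#' @rdname meValue
#' @export
setMethod("meValue", "numeric", function(object) {
  stopifnot(length(object) == 1L, is.finite(object), object > 0)
  object
})

#' Method that produced an Me estimate
#'
#' @param object a [MeEstimate-class].
#' @return one of "weights", "matrix_mean", "closed_form", "grm_variance".
#' @export
setGeneric("meMethod", function(object) standardGeneric("meMethod"))

#' @rdname meMethod
#' @export
setMethod("meMethod", "MeEstimate", function(object) object@method)

#' Individual ids stored in a container
#'
#' @param object a [Grm-class] or [GenotypeMatrix-class].
#' @return character vector of individual ids.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "Grm", function(object) rownames(object@values))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(object) rownames(object@dosages))

#' Dosage matrix of a GenotypeMatrix
#'
#' @param object a [GenotypeMatrix-class].
#' @return numeric matrix of allele dosages (individuals x SNPs).
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeMatrix", function(object) object@dosages)

#' Per-SNP allele frequencies
#'
#' @param object a [GenotypeMatrix-class].
#' @return numeric vector of counted-allele frequencies.
#' @export
setGeneric("alleleFreq", function(object) standardGeneric("alleleFreq"))

#' @rdname alleleFreq
#' @export
setMethod("alleleFreq", "GenotypeMatrix", function(object) object@alleleFreq)

#' @describeIn Grm-class the relationship matrix as a base matrix.
#' @param x a Grm or SnpCorrelationMatrix object.
#' @param ... unused.
#' @export
setMethod("as.matrix", "Grm", function(x, ...) x@values)

#' @describeIn SnpCorrelationMatrix-class the squared-correlation matrix as a
#'   base matrix.
#' @param x the object.
#' @param ... unused.
#' @export
setMethod("as.matrix", "SnpCorrelationMatrix", function(x, ...) x@values)

#' @describeIn GenotypeMatrix-class the dosage matrix as a base matrix.
#' @param x the object.
#' @param ... unused.
#' @export
setMethod("as.matrix", "GenotypeMatrix", function(x, ...) x@dosages)
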