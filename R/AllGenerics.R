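#' @import methods
NULL

#' Omic level of an object
#'
#' @param x An object carrying an omic-level tag.
#' @return A character scalar, one of `"cnv"`, `"mrna"`, `"protein"`,
#'   `"phosphosite"`.
#' @export
setGeneric("omicsLevel", function(x) standardGeneric("omicsLevel"))

#' Feature keys of an object
#'
#' @param x An object with a feature axis.
#' @return Character vector of feature keys.
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' Sample identifiers of an object
#'
#' @param x An object with a sample axis.
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Gene sets held by a collection
#'
#' @param x A [GeneSetCollection-class] object.
#' @return Named list of character vectors of gene symbols.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
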