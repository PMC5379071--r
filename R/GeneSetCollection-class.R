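#' GeneSetCollection: named gene sets
#'
#' A light container for named gene sets (pathways, a druggable-gene list)
#' as read from GMT files: each set is a character vector of gene symbols
#' with an optional free-text description.
#'
#' @slot sets Named list of character vectors (unique, non-empty).
#' @slot description Named character vector of set descriptions.
#'
#' @examples
#' gsc <- GeneSetCollection(list(PathA = c("G1", "G2")))
#' geneSets(gsc)[["PathA"]]
#'
#' @aliases GeneSetCollection
#' @export
setClass("GeneSetCollection",
  slots = c(sets = "list", description = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == ""))
      msg <- c(msg, "set names must be present and unique")
    if (!all(vapply(s, is.character, logical(1))))
      msg <- c(msg, "each set must be a character vector of gene symbols")
    if (any(lengths(s) == 0L))
      msg <- c(msg, "empty gene sets are not allowed")
  }
  if (length(object@description) != length(s))
    msg <- c(msg, "one description per set required")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param description Optional character vector of descriptions, recycled
#'   to empty strings.
#' @return A [GeneSetCollection-class] object.
#' @export
GeneSetCollection <- function(sets, description = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(description)) description <- rep("", length(sets))
  names(description) <- names(sets)
  new("GeneSetCollection", sets = sets, description = description)
}

#' @describeIn GeneSetCollection-class The named list of gene sets.
#' @param x A `GeneSetCollection`.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection-class Number of sets.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class Set names.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' Extract one gene set by name or index
#' @param x A [GeneSetCollection-class].
#' @param i Set name or index.
#' @return Character vector of gene symbols.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %s\n",
    length(object@sets),
    if (length(object@sets))
      paste(range(lengths(object@sets)), collapse = "-") else "-"))
})
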