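#' OmicsMatrix: one omic level's feature-by-sample grid
#'
#' An `OmicsMatrix` holds the value grid of a single omic level together
#' with its level tag. It extends
#' [SummarizedExperiment::SummarizedExperiment-class] with a single assay
#' named `"values"`, so the usual `assay()`, `dim()`, `[` and `colData()`
#' machinery applies. Units by level: log-R ratio (`cnv`), log2 abundance
#' (`mrna`), log2 ratio to a common reference (`protein`, `phosphosite`).
#' Missing measurements are `NA` cells.
#'
#' Feature key conventions: plain gene symbols for `cnv`; gene symbols or
#' `GENE|isoform` keys for `mrna`/`protein` before gene collapsing;
#' `GENE:residue+position` (e.g. `AKT1:S473`) for `phosphosite`.
#'
#' @slot level Character scalar level tag.
#'
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' om <- OmicsMatrix(m, "protein")
#' omicsLevel(om)
#' features(om)
#'
#' @aliases OmicsMatrix
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  slots = c(level = "character")
)

.OMICS_LEVELS <- c("cnv", "mrna", "protein", "phosphosite")

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@level) != 1L || !object@level %in% .OMICS_LEVELS)
    msg <- c(msg, sprintf(
      "'level' must be one of %s", paste(.OMICS_LEVELS, collapse = ", ")))
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  rn <- rownames(object)
  if (nrow(object) > 0L && (is.null(rn) || anyDuplicated(rn)))
    msg <- c(msg, "feature keys must be present and unique")
  cn <- colnames(object)
  if (ncol(object) > 0L && (is.null(cn) || anyDuplicated(cn)))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values Numeric matrix, features in rows (unique rownames), samples
#'   in columns (unique colnames). `NA` marks missing cells.
#' @param level Omic level tag: `"cnv"`, `"mrna"`, `"protein"` or
#'   `"phosphosite"`.
#' @return An [OmicsMatrix-class] object.
#' @export
OmicsMatrix <- function(values, level) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values))
  new("OmicsMatrix", se, level = level)
}

#' @describeIn OmicsMatrix-class Level tag accessor.
#' @param x An `OmicsMatrix`.
#' @export
setMethod("omicsLevel", "OmicsMatrix", function(x) x@level)

#' @describeIn OmicsMatrix-class Feature keys (rownames).
#' @export
setMethod("features", "OmicsMatrix", function(x) rownames(x))

#' @describeIn OmicsMatrix-class Sample ids (colnames).
#' @export
setMethod("sampleIds", "OmicsMatrix", function(x) colnames(x))

#' Extract the value grid of an OmicsMatrix
#'
#' @param x An [OmicsMatrix-class].
#' @return The numeric feature-by-sample matrix (assay `"values"`).
#' @export
omicsValues <- function(x) {
  stopifnot(is(x, "OmicsMatrix"))
  SummarizedExperiment::assay(x, "values")
}

#' Replace the value grid, keeping the level tag
#' @noRd
setOmicsValues <- function(x, values) {
  OmicsMatrix(values, omicsLevel(x))
}

setMethod("show", "OmicsMatrix", function(object) {
  v <- omicsValues(object)
  cat(sprintf(
    "OmicsMatrix [%s]: %d features x %d samples (%.1f%% missing)\n",
    object@level, nrow(v), ncol(v), 100 * mean(is.na(v))))
})
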