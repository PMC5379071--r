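# Shared internal test wrappers.
#
# Sidedness and exactness policy: two-sided throughout; exact null
# distributions when both group sizes are <= 10 (enumeration is cheap and
# the normal approximation is poor there), asymptotic otherwise with
# continuity correction for the rank-sum test. Ties force the approximate
# path (average ranks).

#' @noRd
.rankSumTest <- function(inVals, outVals) {
  nIn <- length(inVals)
  nOut <- length(outVals)
  exact <- nIn <= 10L && nOut <= 10L
  ht <- suppressWarnings(stats::wilcox.test(inVals, outVals,
    alternative = "two.sided", exact = exact, correct = TRUE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # fully tied pooled values: no rank signal
  list(
    # report the classical rank sum of the in-group, not the U statistic
    statistic = unname(ht$statistic) + nIn * (nIn + 1) / 2,
    p = p,
    direction = if (stats::median(inVals) >= stats::median(outVals))
      "up" else "down")
}

#' @noRd
.ksTest <- function(inVals, outVals) {
  exact <- length(inVals) <= 10L && length(outVals) <= 10L
  ht <- suppressWarnings(stats::ks.test(inVals, outVals,
    alternative = "two.sided", exact = exact))
  list(
    statistic = unname(ht$statistic),
    p = ht$p.value,
    direction = if (stats::median(inVals) >= stats::median(outVals))
      "high" else "low")
}

#' @noRd
.phosphoGene <- function(keys) {
  gene <- sub(":.*$", "", keys)
  bad <- which(!grepl(":", keys, fixed = TRUE) | !nzchar(gene))
  if (length(bad))
    stop("phosphosite key not of the form GENE:site at row ", bad[1L],
      ": '", keys[bad[1L]], "'")
  gene
}

#' @noRd
.sdNa <- function(x) stats::sd(x, na.rm = TRUE)
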