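#' Per-feature differential expression between two groups
#'
#' Two-sample t-test per feature on non-missing values, BH-adjusted
#' across all tested features. Welch's unequal-variance form is the
#' default; `varEqual = TRUE` gives the pooled-variance test (the sign of
#' t is unaffected by the choice).
#'
#' @param x An [OmicsMatrix-class].
#' @param groups Named character/factor of group labels (exactly two
#'   levels) for the samples of `x`, or a vector in sample order.
#' @param varEqual Use the pooled-variance t-test (default FALSE).
#' @return `data.frame` with `feature`, the two group means, `diff`
#'   (group1 - group2), `t`, `p`, `q`, `n1`, `n2`. Features with fewer
#'   than 3 values in either group are skipped (listed in the `skipped`
#'   attribute).
#' @export
differentialTest <- function(x, groups, varEqual = FALSE) {
  stopifnot(is(x, "OmicsMatrix"))
  v <- omicsValues(x)
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(v), names(groups))
    if (length(miss))
      stop("samples without group label: ", paste(miss, collapse = ", "))
    groups <- groups[colnames(v)]
  } else if (length(groups) != ncol(v)) {
    stop("'groups' must label every sample")
  }
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required")
  g1 <- groups == lev[1L]
  if (sum(g1) < 3L || sum(!g1) < 3L)
    stop("both groups need at least 3 samples")
  rows <- list(); skipped <- character()
  for (i in seq_len(nrow(v))) {
    a <- v[i, g1]; a <- a[!is.na(a)]
    b <- v[i, !g1]; b <- b[!is.na(b)]
    if (length(a) < 3L || length(b) < 3L) {
      skipped <- c(skipped, rownames(v)[i])
      next
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: identical constants give t = 0, p = 1; differing
      # constants are an infinite-t separation reported as p = 0
      tt <- if (mean(a) == mean(b)) list(statistic = 0, p.value = 1)
        else list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0)
    } else {
      ht <- stats::t.test(a, b, var.equal = varEqual)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature = rownames(v)[i], mean1 = mean(a), mean2 = mean(b),
      diff = mean(a) - mean(b), t = tt$statistic, p = tt$p.value,
      n1 = length(a), n2 = length(b), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), mean1 = numeric(),
      mean2 = numeric(), diff = numeric(), t = numeric(), p = numeric(),
      n1 = integer(), n2 = integer(), stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("feature", "mean1", "mean2", "diff", "t", "p", "q",
    "n1", "n2")]
  names(out)[2:3] <- paste0("mean_", lev)
  rownames(out) <- NULL
  attr(out, "groups") <- lev
  attr(out, "skipped") <- skipped
  out
}

#' Rank-based gene-set enrichment of differential t-statistics
#'
#' Per gene set, a two-sided Wilcoxon rank-sum test of the member genes'
#' t-statistics against all non-member t-statistics, BH-adjusted across
#' sets. Captures coordinated shifts of a pathway in the differential
#' ranking without requiring individual genes to pass a cutoff.
#'
#' @param differential Output of [differentialTest()].
#' @param sets A [GeneSetCollection-class].
#' @param minSize Minimum member genes with t-statistics (default 5).
#' @return `data.frame` with `set`, `statistic` (in-set rank sum), `p`,
#'   `q`, `direction` (`up`/`down` by median t difference), `n_in`,
#'   `n_background`. Skipped sets in the `skipped` attribute.
#' @export
rankedGeneSetEnrichment <- function(differential, sets, minSize = 5L) {
  stopifnot(is(sets, "GeneSetCollection"))
  tstat <- differential$t
  names(tstat) <- differential$feature
  tstat <- tstat[is.finite(tstat)]
  rows <- list(); skipped <- character()
  for (nm in names(geneSets(sets))) {
    inSet <- names(tstat) %in% sets[[nm]]
    if (sum(inSet) < minSize) {
      skipped <- c(skipped, nm)
      next
    }
    rs <- .rankSumTest(tstat[inSet], tstat[!inSet])
    rows[[nm]] <- data.frame(set = nm, statistic = rs$statistic,
      p = rs$p, direction = rs$direction, n_in = sum(inSet),
      n_background = sum(!inSet), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), statistic = numeric(), p = numeric(),
      direction = character(), n_in = integer(),
      n_background = integer(), stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("set", "statistic", "p", "q", "direction", "n_in",
    "n_background")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
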