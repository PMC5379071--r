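#' Per-gene mRNA-protein correlation
#'
#' For every gene present in both layers and observed in at least
#' `minFrac` of the samples in each layer, computes the rank (Spearman)
#' correlation between mRNA and protein values over pairwise-complete
#' samples. Spearman is the default because the two layers are measured
#' on different scales; the Pearson coefficient is reported alongside for
#' comparison with studies that summarise the linear correlation.
#'
#' @param mrna,protein Gene-level [OmicsMatrix-class] objects sharing the
#'   sample axis.
#' @param minFrac Minimum fraction of samples a gene must be observed in,
#'   per layer (default 0.30; the required count is
#'   `ceiling(minFrac * n)`).
#' @param method Correlation reported in the `rho` column
#'   (`"spearman"` default or `"pearson"`).
#' @return `data.frame` with columns `gene`, `rho`, `spearman`,
#'   `pearson`, `n_pairs`, `method`. Genes failing the observation filter
#'   or with fewer than 3 pairwise-complete samples (or zero variance)
#'   are excluded; counts are in the `filtered` attribute.
#' @export
geneCorrelation <- function(mrna, protein, minFrac = 0.30,
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(is(mrna, "OmicsMatrix"), is(protein, "OmicsMatrix"))
  if (!identical(sampleIds(mrna), sampleIds(protein)))
    stop("matrices must share the sample axis")
  vm <- omicsValues(mrna)
  vp <- omicsValues(protein)
  shared <- intersect(rownames(vm), rownames(vp))
  if (!length(shared)) stop("no shared genes between the two layers")
  n <- ncol(vm)
  need <- ceiling(minFrac * n)
  vm <- vm[shared, , drop = FALSE]
  vp <- vp[shared, , drop = FALSE]
  okObs <- rowSums(!is.na(vm)) >= need & rowSums(!is.na(vp)) >= need
  dropped <- c(observation_filter = sum(!okObs), degenerate = 0L)
  res <- lapply(which(okObs), function(i) {
    cc <- stats::complete.cases(vm[i, ], vp[i, ])
    x <- vm[i, cc]; y <- vp[i, cc]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NULL)
    data.frame(gene = shared[i],
      spearman = stats::cor(x, y, method = "spearman"),
      pearson = stats::cor(x, y, method = "pearson"),
      n_pairs = length(x), stringsAsFactors = FALSE)
  })
  keep <- !vapply(res, is.null, logical(1))
  dropped[["degenerate"]] <- sum(!keep)
  out <- do.call(rbind, res[keep])
  rownames(out) <- NULL
  out$rho <- if (method == "spearman") out$spearman else out$pearson
  out$method <- method
  out <- out[, c("gene", "rho", "spearman", "pearson", "n_pairs",
    "method")]
  attr(out, "filtered") <- dropped
  out
}

#' Pathway enrichment of the correlation ranking
#'
#' Tests, per pathway, whether the mRNA-protein correlations of member
#' genes differ in distribution from the non-member background using a
#' two-sample two-sided Kolmogorov-Smirnov test; p-values are adjusted
#' across all tested pathways by Benjamini-Hochberg.
#'
#' @param correlations Output of [geneCorrelation()].
#' @param pathways A [GeneSetCollection-class].
#' @param minSize Minimum member genes with correlation results required
#'   to test a pathway (default 5; smaller sets are skipped).
#' @return `data.frame` with `set`, `statistic` (KS D), `p`, `q`,
#'   `direction` (`high`/`low`: median in-set rho above/below the
#'   background median), `n_in`, `n_background`. Skipped sets are listed
#'   in the `skipped` attribute.
#' @export
ksPathwayEnrichment <- function(correlations, pathways, minSize = 5L) {
  stopifnot(is(pathways, "GeneSetCollection"))
  rho <- correlations$rho
  names(rho) <- correlations$gene
  sets <- geneSets(pathways)
  rows <- list(); skipped <- character()
  for (nm in names(sets)) {
    inSet <- names(rho) %in% sets[[nm]]
    if (sum(inSet) < minSize) {
      skipped <- c(skipped, nm)
      next
    }
    if (!any(!inSet)) stop("empty background for set ", nm)
    ks <- .ksTest(rho[inSet], rho[!inSet])
    rows[[nm]] <- data.frame(set = nm, statistic = ks$statistic,
      p = ks$p, direction = ks$direction, n_in = sum(inSet),
      n_background = sum(!inSet), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), statistic = numeric(), p = numeric(),
      direction = character(), n_in = integer(),
      n_background = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("set", "statistic", "p", "q", "direction", "n_in",
    "n_background")]
  attr(out, "skipped") <- skipped
  out
}
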