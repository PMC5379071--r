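#' Collapse phosphosites to gene-level phosphorylation values
#'
#' Per (gene, sample), the mean of the gene's observed site values
#' (`GENE:site` keys); missing when no site of the gene is observed in
#' that sample.
#'
#' @param x An [OmicsMatrix-class] with level `phosphosite`.
#' @return A gene-keyed [OmicsMatrix-class] (level kept as
#'   `phosphosite`), gene order following first appearance.
#' @export
collapsePhosphoToGene <- function(x) {
  stopifnot(is(x, "OmicsMatrix"), omicsLevel(x) == "phosphosite")
  v <- omicsValues(x)
  gene <- .phosphoGene(rownames(v))
  ug <- unique(gene)
  gi <- match(gene, ug)
  obs <- !is.na(v)
  vz <- v
  vz[!obs] <- 0
  sums <- rowsum(vz, gi, reorder = FALSE)
  counts <- rowsum(obs + 0, gi, reorder = FALSE)
  out <- sums / counts  # 0/0 -> NaN where no site observed
  out[counts == 0] <- NA_real_
  dimnames(out) <- list(ug, colnames(v))
  setOmicsValues(x, out)
}

#' Modified z-scores against the cohort
#'
#' Robust per-gene standardisation across the cohort:
#' \deqn{M = 0.6745 (x - \tilde{x}) / \mathrm{MAD}}
#' where \eqn{\tilde{x}} is the gene's cohort median and MAD the median
#' absolute deviation from it. When MAD = 0 the mean-absolute-deviation
#' alternative \eqn{M = 0.7979 (x - \tilde{x}) / \mathrm{meanAD}} is used;
#' if that is also 0 the gene's scores are 0 (basis `"undefined"`). The
#' basis actually used is recorded per gene.
#'
#' @param x A gene-level [OmicsMatrix-class] (e.g. from
#'   [collapsePhosphoToGene()]).
#' @param minObs Minimum non-missing cohort values per gene (default 10);
#'   genes below it are dropped (listed in the `dropped` attribute).
#' @return List with `z` (gene-by-sample matrix of modified z-scores,
#'   `NA` where unobserved) and `basis` (named character per gene:
#'   `mad`, `meanad` or `undefined`).
#' @export
modifiedZscore <- function(x, minObs = 10L) {
  stopifnot(is(x, "OmicsMatrix"))
  v <- omicsValues(x)
  keep <- rowSums(!is.na(v)) >= minObs
  dropped <- rownames(v)[!keep]
  v <- v[keep, , drop = FALSE]
  z <- v
  basis <- stats::setNames(rep("undefined", nrow(v)), rownames(v))
  for (i in seq_len(nrow(v))) {
    xi <- v[i, ]
    med <- stats::median(xi, na.rm = TRUE)
    dev <- xi - med
    mad0 <- stats::median(abs(dev), na.rm = TRUE)
    if (!is.na(mad0) && mad0 > 0) {
      z[i, ] <- 0.6745 * dev / mad0
      basis[i] <- "mad"
    } else {
      meanad <- mean(abs(dev), na.rm = TRUE)
      if (!is.na(meanad) && meanad > 0) {
        z[i, ] <- 0.7979 * dev / meanad
        basis[i] <- "meanad"
      } else {
        z[i, ] <- ifelse(is.na(xi), NA_real_, 0)
      }
    }
  }
  structure(list(z = z, basis = basis), dropped = dropped)
}

#' Per-sample pathway activation from phosphorylation z-scores
#'
#' Within each sample, tests every pathway's member-gene modified
#' z-scores against all non-member z-scores with a two-sided Wilcoxon
#' rank-sum test; p-values are BH-adjusted across all (sample, pathway)
#' tests of the run (set `perSample = TRUE` to adjust within each sample
#' instead). A pathway is flagged activated in a sample at
#' q <= `fdr` with a positive median member z-score.
#'
#' @param zscores Output of [modifiedZscore()] (or a bare z matrix).
#' @param pathways A [GeneSetCollection-class].
#' @param minGenes Minimum member genes with z-scores per (sample,
#'   pathway) test (default 5; smaller tests are skipped).
#' @param fdr Activation FDR threshold (default 0.01).
#' @param perSample Adjust p-values within each sample separately.
#' @return `data.frame` with `sample`, `pathway`, `n_members`,
#'   `median_z`, `statistic` (member rank sum), `p`, `q`, `activated`.
#' @export
pathwayActivation <- function(zscores, pathways, minGenes = 5L,
                              fdr = 0.01, perSample = FALSE) {
  stopifnot(is(pathways, "GeneSetCollection"))
  z <- if (is.list(zscores)) zscores$z else zscores
  sets <- geneSets(pathways)
  rows <- list()
  for (s in colnames(z)) {
    zs <- z[, s]
    zs <- zs[!is.na(zs)]
    for (nm in names(sets)) {
      inSet <- names(zs) %in% sets[[nm]]
      if (sum(inSet) < minGenes || !any(!inSet)) next
      rs <- .rankSumTest(zs[inSet], zs[!inSet])
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, pathway = nm, n_members = sum(inSet),
        median_z = stats::median(zs[inSet]), statistic = rs$statistic,
        p = rs$p, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), pathway = character(),
      n_members = integer(), median_z = numeric(), statistic = numeric(),
      p = numeric(), stringsAsFactors = FALSE)
  out$q <- if (perSample)
    stats::ave(out$p, out$sample,
      FUN = function(p) stats::p.adjust(p, "BH"))
  else stats::p.adjust(out$p, method = "BH")
  out$activated <- out$q <= fdr & out$median_z > 0
  rownames(out) <- NULL
  out
}
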