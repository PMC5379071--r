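#' Select variably expressed markers
#'
#' Keeps features observed in at least `minObs` samples whose sample
#' standard deviation (over non-missing values) exceeds `sdThreshold`,
#' ordered by descending s.d. Conventional thresholds are 2 s.d. for an
#' isobaric-label proteome and 2.5 s.d. for a phosphoproteome.
#'
#' @param x An [OmicsMatrix-class].
#' @param sdThreshold Positive s.d. cutoff (strict inequality).
#' @param minObs Minimum non-missing values per feature (default 10).
#' @return Character vector of feature keys, descending s.d.; the s.d.
#'   values are carried in the `sd` attribute. May be empty.
#' @export
selectVariableMarkers <- function(x, sdThreshold, minObs = 10L) {
  stopifnot(is(x, "OmicsMatrix"), sdThreshold > 0)
  v <- omicsValues(x)
  nObs <- rowSums(!is.na(v))
  sds <- apply(v, 1L, .sdNa)
  keep <- which(nObs >= minObs & !is.na(sds) & sds > sdThreshold)
  ord <- keep[order(sds[keep], decreasing = TRUE)]
  structure(rownames(v)[ord], sd = unname(sds[ord]))
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Clusters samples on the selected marker features with complete-linkage
#' agglomeration. The default distance is euclidean over pairwise-complete
#' markers with proportional rescaling (the summed squared difference over
#' mutually observed markers is scaled by n_markers / n_observed before
#' the square root, as in [stats::dist()]); `distance = "pearson"` uses
#' 1 - Pearson correlation on pairwise-complete markers instead. Rows are
#' median-centered by default; set `scaleRows = TRUE` to also divide by
#' the row s.d.
#'
#' @param x An [OmicsMatrix-class].
#' @param markers Character vector of feature keys to cluster on (e.g.
#'   from [selectVariableMarkers()]); `NULL` uses all features.
#' @param k Number of clusters to cut the tree at (default 2).
#' @param distance `"euclidean"` (default) or `"pearson"`.
#' @param centerRows Median-center each marker row first (default TRUE).
#' @param scaleRows Additionally scale rows to unit s.d. (default FALSE).
#' @return List (class `ClusteringResult`) with `labels` (named integer
#'   cluster labels at cut `k`), `tree` (the [stats::hclust] object),
#'   `markers`, `k` and `level`.
#' @export
clusterSamples <- function(x, markers = NULL, k = 2L,
                           distance = c("euclidean", "pearson"),
                           centerRows = TRUE, scaleRows = FALSE) {
  distance <- match.arg(distance)
  stopifnot(is(x, "OmicsMatrix"), k >= 1L)
  v <- omicsValues(x)
  if (!is.null(markers)) {
    miss <- setdiff(markers, rownames(v))
    if (length(miss))
      stop("markers absent from matrix: ", paste(miss, collapse = ", "))
    v <- v[markers, , drop = FALSE]
  }
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("need at least 2 markers and 2 samples")
  if (centerRows)
    v <- v - apply(v, 1L, stats::median, na.rm = TRUE)
  if (scaleRows) {
    s <- apply(v, 1L, .sdNa)
    s[is.na(s) | s == 0] <- 1
    v <- v / s
  }
  d <- if (distance == "euclidean") {
    stats::dist(t(v))  # NA-aware: scales the sum by n/n_obs
  } else {
    cc <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
    stats::as.dist(1 - cc)
  }
  dm <- as.matrix(d)
  if (any(is.na(dm))) {
    ij <- which(is.na(dm), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "no mutually observed markers between samples '%s' and '%s'",
      rownames(dm)[ij[1]], colnames(dm)[ij[2]]))
  }
  tree <- stats::hclust(d, method = "complete")
  labels <- stats::cutree(tree, k = k)
  structure(list(labels = labels, tree = tree,
    markers = rownames(v), k = k, level = omicsLevel(x)),
    class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf(
    "ClusteringResult [%s]: %d samples, %d markers, k = %d (sizes: %s)\n",
    x$level, length(x$labels), length(x$markers), x$k,
    paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Export a sample dendrogram as Newick
#'
#' @param result A `ClusteringResult` from [clusterSamples()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
exportNewick <- function(result, path) {
  stopifnot(inherits(result, "ClusteringResult"))
  ape::write.tree(ape::as.phylo(result$tree), file = path)
  invisible(path)
}

#' Markers suitable for PDX/human co-clustering
#'
#' Joint clustering of xenograft and human proteomes is confounded by
#' systematic xenograft-vs-human differences (for example stromal species
#' composition). This filter keeps genes that (i) show no differential
#' expression between the two cohorts (two-sample t-test, BH-adjusted
#' q > `fdrFloor`), (ii) vary enough in the merged proteome
#' (s.d. > `sdThreshold`) and (iii) are observed in more than `minObs`
#' merged samples.
#'
#' @param pdx,human Gene-level protein [OmicsMatrix-class] objects with a
#'   shared gene space (intersected).
#' @param fdrFloor Keep genes with BH q strictly above this (default 0.3).
#' @param sdThreshold Merged-proteome s.d. cutoff (default 2).
#' @param minObs Merged observation cutoff, strict (default 10).
#' @return List with `markers` (character vector) and `stats` (per-gene
#'   `data.frame`: `gene`, `t`, `p`, `q`, `sd_merged`, `n_merged`,
#'   `selected`).
#' @export
coClusteringMarkers <- function(pdx, human, fdrFloor = 0.3,
                                sdThreshold = 2, minObs = 10L) {
  stopifnot(is(pdx, "OmicsMatrix"), is(human, "OmicsMatrix"))
  vp <- omicsValues(pdx)
  vh <- omicsValues(human)
  shared <- intersect(rownames(vp), rownames(vh))
  if (!length(shared)) stop("no shared genes between cohorts")
  vp <- vp[shared, , drop = FALSE]
  vh <- vh[shared, , drop = FALSE]
  tt <- vapply(seq_along(shared), function(i) {
    a <- vp[i, !is.na(vp[i, ])]
    b <- vh[i, !is.na(vh[i, ])]
    if (length(a) < 3L || length(b) < 3L ||
        (stats::sd(a) == 0 && stats::sd(b) == 0))
      return(c(NA_real_, NA_real_))
    ht <- stats::t.test(a, b)
    c(unname(ht$statistic), ht$p.value)
  }, numeric(2))
  merged <- cbind(vp, vh)
  sdM <- apply(merged, 1L, .sdNa)
  nM <- rowSums(!is.na(merged))
  q <- stats::p.adjust(tt[2L, ], method = "BH")
  stats <- data.frame(gene = shared, t = tt[1L, ], p = tt[2L, ], q = q,
    sd_merged = sdM, n_merged = nM, stringsAsFactors = FALSE)
  stats$selected <- !is.na(q) & q > fdrFloor &
    !is.na(sdM) & sdM > sdThreshold & nM > minObs
  rownames(stats) <- NULL
  list(markers = stats$gene[stats$selected], stats = stats)
}
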