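#' IQR-based expression outlier score
#'
#' For one feature's values across the cohort, the outlier score of a
#' sample is \eqn{O = (x - Q3) / IQR}, with quartiles computed over the
#' feature's non-missing cohort values by linear interpolation between
#' order statistics (`h = (n - 1) p`, [stats::quantile()] type 7). A value
#' is an expression outlier when it lies more than 1.5 IQRs above the
#' third quartile, i.e. exactly when O > 1.5. With a degenerate spread
#' (IQR = 0) any value above Q3 is reported as `Inf` (still an outlier by
#' the definition) and values at or below Q3 score 0. Only the high side
#' is scored: the analysis targets overexpression/hyperactivation.
#'
#' @param x Numeric vector of one feature's cohort values (`NA` allowed;
#'   missing values receive no score).
#' @return List with `score` (same length as `x`), `q1`, `q3`, `iqr`,
#'   `n_obs`.
#' @export
outlierScore <- function(x) {
  obs <- x[!is.na(x)]
  n <- length(obs)
  if (n == 0L)
    return(list(score = x, q1 = NA_real_, q3 = NA_real_,
      iqr = NA_real_, n_obs = 0L))
  q <- stats::quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  score <- if (iqr > 0) {
    (x - q[2L]) / iqr
  } else {
    ifelse(x > q[2L], Inf, 0)
  }
  list(score = score, q1 = q[1L], q3 = q[2L], iqr = iqr, n_obs = n)
}

.OUTLIER_THRESHOLD <- 1.5

#' Call druggable expression outliers across omic levels
#'
#' Restricts each supplied level to features of druggable genes
#' (phosphosites inherit druggability from the gene symbol in their
#' `GENE:site` key), requires each feature to be observed in at least
#' `minObs` samples, scores every observed cell with [outlierScore()] and
#' ranks calls within each (sample, level) by descending score. CNV calls
#' are flagged `cnv_cross_validated` only when the same gene scores above
#' `crossThreshold` at the mRNA or protein level in the same sample,
#' guarding against copy-number outliers that never propagate to
#' expression.
#'
#' @param matrices Named list of [OmicsMatrix-class] objects keyed by
#'   level (any subset of cnv/mrna/protein/phosphosite), sharing the
#'   sample axis.
#' @param druggable Character vector of druggable gene symbols.
#' @param minObs Observation filter per feature (default 10).
#' @param scoreThreshold Outlier definition threshold (default 1.5).
#' @param crossThreshold CNV cross-validation threshold on the other
#'   expression levels (default 1, strict inequality).
#' @return `data.frame` of outlier calls: `sample`, `feature`, `gene`,
#'   `level`, `value`, `q1`, `q3`, `iqr`, `score`, `rank` (unique within
#'   sample x level), `is_outlier`, `cnv_cross_validated` (`NA` for
#'   non-CNV rows).
#' @export
callOutliers <- function(matrices, druggable, minObs = 10L,
                         scoreThreshold = .OUTLIER_THRESHOLD,
                         crossThreshold = 1) {
  stopifnot(is.list(matrices), length(matrices) >= 1L,
    length(druggable) >= 1L)
  bad <- setdiff(names(matrices), .OMICS_LEVELS)
  if (length(bad)) stop("unknown levels: ", paste(bad, collapse = ", "))
  scored <- list()
  seen <- character()
  for (lv in names(matrices)) {
    v <- omicsValues(matrices[[lv]])
    gene <- if (lv == "phosphosite")
      .phosphoGene(rownames(v)) else sub("\\|.*$", "", rownames(v))
    hit <- gene %in% druggable
    seen <- union(seen, gene[hit])
    v <- v[hit, , drop = FALSE]
    gene <- gene[hit]
    if (!nrow(v)) next
    keep <- rowSums(!is.na(v)) >= minObs
    v <- v[keep, , drop = FALSE]
    gene <- gene[keep]
    if (!nrow(v)) next
    rows <- lapply(seq_len(nrow(v)), function(i) {
      sc <- outlierScore(v[i, ])
      obs <- !is.na(v[i, ])
      data.frame(sample = colnames(v)[obs], feature = rownames(v)[i],
        gene = gene[i], level = lv, value = v[i, obs],
        q1 = sc$q1, q3 = sc$q3, iqr = sc$iqr,
        score = sc$score[obs], stringsAsFactors = FALSE)
    })
    scored[[lv]] <- do.call(rbind, rows)
  }
  missing <- setdiff(druggable, seen)
  if (length(missing))
    warning("druggable genes absent from all matrices: ",
      paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  if (!length(scored))
    return(data.frame(sample = character(), feature = character(),
      gene = character(), level = character(), value = numeric(),
      q1 = numeric(), q3 = numeric(), iqr = numeric(), score = numeric(),
      rank = integer(), is_outlier = logical(),
      cnv_cross_validated = logical(), stringsAsFactors = FALSE))
  calls <- do.call(rbind, scored)
  rownames(calls) <- NULL
  # unique within-sample rank by descending score (ties broken stably)
  calls <- calls[order(calls$level, calls$sample, -calls$score,
    calls$feature), ]
  calls$rank <- stats::ave(calls$score,
    calls$level, calls$sample,
    FUN = function(s) seq_along(s))
  calls$is_outlier <- calls$score > scoreThreshold
  calls$cnv_cross_validated <- NA
  if ("cnv" %in% calls$level) {
    expr <- calls[calls$level %in% c("mrna", "protein"), ]
    key <- paste(expr$sample, expr$gene)
    validated <- unique(key[expr$score > crossThreshold])
    isCnv <- calls$level == "cnv"
    calls$cnv_cross_validated[isCnv] <-
      paste(calls$sample[isCnv], calls$gene[isCnv]) %in% validated
  }
  rownames(calls) <- NULL
  calls
}

#' Validate PDX outlier calls in a human cohort
#'
#' A PDX outlier event is human-validated when at least one human sample
#' shows, for the same feature and level, either an outlier score above
#' `scoreFloor` or that feature among the sample's top `topK` scores
#' (within the level). Features not quantified (or under-observed) in the
#' human cohort are annotated not-assessable and excluded from the rate
#' denominator.
#'
#' @param pdxCalls Output of [callOutliers()] on the PDX cohort.
#' @param humanMatrices Named list of human [OmicsMatrix-class] objects
#'   keyed by level.
#' @param druggable Druggable gene list used for the human scoring.
#' @param minObs Observation filter in the human cohort (default 10).
#' @param scoreFloor Human outlier-score criterion (default 1, strict).
#' @param topK Per-sample top-rank criterion (default 2).
#' @return List with `calls` (PDX outlier rows annotated with
#'   `human_validated` and `assessable`) and `rates` (per level:
#'   validated / assessable outlier events).
#' @export
humanValidation <- function(pdxCalls, humanMatrices, druggable,
                            minObs = 10L, scoreFloor = 1, topK = 2L) {
  humanCalls <- suppressWarnings(
    callOutliers(humanMatrices, druggable, minObs = minObs))
  out <- pdxCalls[pdxCalls$is_outlier, , drop = FALSE]
  validKey <- unique(paste(
    humanCalls$level, humanCalls$feature
  )[humanCalls$score > scoreFloor | humanCalls$rank <= topK])
  presentKey <- unique(paste(humanCalls$level, humanCalls$feature))
  key <- paste(out$level, out$feature)
  out$assessable <- key %in% presentKey
  out$human_validated <- out$assessable & key %in% validKey
  rates <- vapply(split(out, out$level), function(d) {
    a <- d[d$assessable, , drop = FALSE]
    if (!nrow(a)) NA_real_ else mean(a$human_validated)
  }, numeric(1))
  list(calls = out, rates = rates)
}

#' Census of druggable somatic mutations
#'
#' Restricts a mutation table to genes on the druggable list, groups the
#' events by sample and counts the distinct samples carrying at least one
#' druggable mutation. The fraction is reported against the number of
#' distinct samples in the table and, when given, against `cohortSize`.
#'
#' @param mutations Mutation `data.frame` (see [readMutations()]).
#' @param druggable Character vector of druggable gene symbols.
#' @param cohortSize Optional total cohort size for the fraction.
#' @return List with `events` (the druggable mutation rows),
#'   `bySample` (list of per-sample event tables), `nSamples` (distinct
#'   samples with druggable mutations) and `fraction` (against
#'   `cohortSize`, or `NA`).
#' @export
druggableMutationCensus <- function(mutations, druggable,
                                    cohortSize = NULL) {
  ev <- mutations[mutations$gene %in% druggable, , drop = FALSE]
  rownames(ev) <- NULL
  n <- length(unique(ev$sample))
  list(events = ev,
    bySample = split(ev, ev$sample),
    nSamples = n,
    fraction = if (is.null(cohortSize)) NA_real_ else n / cohortSize)
}
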