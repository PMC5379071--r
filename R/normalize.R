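#' Collapse isoform-level rows to one row per gene
#'
#' mRNA and protein matrices may carry several rows per gene
#' (`GENE|isoform` keys). Collapsing keeps exactly one measured row per
#' gene: a single row passes through; with two rows the row with the higher
#' missing-aware mean is kept; with three or more rows the row with the
#' highest connectivity is kept, where connectivity is the row's summed
#' pairwise Pearson correlation with the gene's other rows computed on
#' pairwise-complete samples. Connectivity ties (and genes whose rows share
#' fewer than 3 pairwise-complete samples) fall back to the highest mean;
#' fallbacks are reported in the `collapse_fallback` attribute.
#'
#' @param x An [OmicsMatrix-class] with level `mrna` or `protein`.
#' @return An [OmicsMatrix-class] with one row per gene (key = gene symbol),
#'   gene order following first appearance in `x`.
#' @export
collapseToGene <- function(x) {
  stopifnot(is(x, "OmicsMatrix"))
  if (!omicsLevel(x) %in% c("mrna", "protein"))
    stop("collapseToGene applies to mrna or protein matrices")
  v <- omicsValues(x)
  genes <- sub("\\|.*$", "", rownames(v))
  ug <- unique(genes)
  out <- matrix(NA_real_, length(ug), ncol(v),
    dimnames = list(ug, colnames(v)))
  fallback <- character()
  for (g in ug) {
    idx <- which(genes == g)
    if (length(idx) == 1L) {
      out[g, ] <- v[idx, ]
      next
    }
    rows <- v[idx, , drop = FALSE]
    means <- rowMeans(rows, na.rm = TRUE)
    if (length(idx) == 2L) {
      out[g, ] <- rows[which.max(means), ]
      next
    }
    cc <- suppressWarnings(stats::cor(t(rows),
      use = "pairwise.complete.obs"))
    nObs <- !is.na(rows)
    pairN <- nObs %*% t(nObs)
    offdiag <- upper.tri(pairN) | lower.tri(pairN)
    if (any(is.na(cc[offdiag])) || any(pairN[offdiag] < 3)) {
      out[g, ] <- rows[which.max(means), ]
      fallback <- c(fallback, g)
      next
    }
    conn <- rowSums(cc) - 1  # drop the self-correlation
    best <- which(conn > max(conn) - 1e-9)
    if (length(best) > 1L) best <- best[which.max(means[best])]
    out[g, ] <- rows[best, ]
  }
  res <- setOmicsValues(x, out)
  attr(res, "collapse_fallback") <- fallback
  res
}

#' Fit a two-component Gaussian mixture to a vector
#'
#' Deterministic EM: means initialised at the 25th/75th percentiles, equal
#' initial weights and standard deviations, tolerance `tol` on the
#' log-likelihood, at most `maxit` iterations. The two-component fit is
#' compared by BIC with the single-Gaussian fit; when one component
#' suffices (as for a column that is already a plain Gaussian) the
#' single-component solution is reported, avoiding the symmetric-split
#' degeneracy of a two-component EM on unimodal data.
#'
#' @param x Numeric vector (NAs dropped).
#' @param tol Log-likelihood convergence tolerance.
#' @param maxit Maximum EM iterations.
#' @return List with `mu`, `sigma`, `pi` (length 2), `dominant` (index of
#'   the higher-weight component), `offset` (dominant component mean),
#'   `converged`, `basis` (`"mixture"`, `"single"` or `"median"`) and
#'   `iterations`.
#' @export
fitGaussianMixture <- function(x, tol = 1e-6, maxit = 500L) {
  x <- x[!is.na(x)]
  n <- length(x)
  med <- stats::median(x)
  s0 <- stats::sd(x)
  fail <- function(basis) list(
    mu = c(med, med), sigma = c(0, 0), pi = c(1, 0), dominant = 1L,
    offset = med, converged = FALSE, basis = basis, iterations = 0L)
  if (n < 4L || !is.finite(s0) || s0 == 0) return(fail("median"))
  mu <- as.numeric(stats::quantile(x, c(0.25, 0.75), type = 7))
  sg <- c(s0, s0)
  pi <- c(0.5, 0.5)
  ll0 <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    d1 <- pi[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- pi[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    if (abs(ll - ll0) < tol) {
      converged <- TRUE
      break
    }
    ll0 <- ll
    r <- d1 / tot
    n1 <- sum(r)
    n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    sg <- c(sqrt(sum(r * (x - mu[1])^2) / n1),
            sqrt(sum((1 - r) * (x - mu[2])^2) / n2))
    sg <- pmax(sg, 1e-8)
    pi <- c(n1, n2) / n
  }
  if (!converged) return(fail("median"))
  # BIC model choice against the one-component fit (k = 5 vs k = 2)
  mle <- c(mean(x), stats::sd(x) * sqrt((n - 1) / n))
  ll1 <- sum(stats::dnorm(x, mle[1], mle[2], log = TRUE))
  bic2 <- -2 * ll + 5 * log(n)
  bic1 <- -2 * ll1 + 2 * log(n)
  if (bic1 <= bic2) {
    return(list(mu = c(mle[1], mle[1]), sigma = c(mle[2], mle[2]),
      pi = c(1, 0), dominant = 1L, offset = mle[1], converged = TRUE,
      basis = "single", iterations = it))
  }
  dominant <- which.max(pi)
  list(mu = mu, sigma = sg, pi = pi, dominant = dominant,
    offset = mu[dominant], converged = TRUE, basis = "mixture",
    iterations = it)
}

#' Mixture-model re-centering of log-ratio columns
#'
#' For each sample column of a protein or phosphosite matrix, fits a
#' two-component Gaussian mixture to the non-missing log-ratios (see
#' [fitGaussianMixture()]) and subtracts the dominant (higher-weight)
#' component's mean, centering the unregulated bulk of the distribution at
#' zero. Columns where the EM does not converge fall back to subtracting
#' the column median (flagged in the fit table). Only the location is
#' corrected; no variance rescaling is applied.
#'
#' @param x An [OmicsMatrix-class] with level `protein` or `phosphosite`.
#' @param minValues Minimum non-missing values required per column.
#' @param tol,maxit EM controls, passed to [fitGaussianMixture()].
#' @return List with `matrix` (the centered [OmicsMatrix-class]) and
#'   `fits`, a per-sample `data.frame` of mixture parameters, the applied
#'   `offset` and the fit `basis`.
#' @export
mixtureCenter <- function(x, minValues = 50L, tol = 1e-6, maxit = 500L) {
  stopifnot(is(x, "OmicsMatrix"))
  if (!omicsLevel(x) %in% c("protein", "phosphosite"))
    stop("mixtureCenter applies to protein or phosphosite matrices")
  v <- omicsValues(x)
  nobs <- colSums(!is.na(v))
  if (any(nobs < minValues))
    stop("columns with fewer than ", minValues, " values: ",
      paste(colnames(v)[nobs < minValues], collapse = ", "))
  fits <- lapply(seq_len(ncol(v)), function(j)
    fitGaussianMixture(v[, j], tol = tol, maxit = maxit))
  offsets <- vapply(fits, `[[`, numeric(1), "offset")
  centered <- sweep(v, 2L, offsets, "-")
  fitdf <- data.frame(
    sample = colnames(v),
    mu1 = vapply(fits, function(f) f$mu[1], numeric(1)),
    mu2 = vapply(fits, function(f) f$mu[2], numeric(1)),
    sigma1 = vapply(fits, function(f) f$sigma[1], numeric(1)),
    sigma2 = vapply(fits, function(f) f$sigma[2], numeric(1)),
    pi1 = vapply(fits, function(f) f$pi[1], numeric(1)),
    pi2 = vapply(fits, function(f) f$pi[2], numeric(1)),
    dominant = vapply(fits, `[[`, integer(1), "dominant"),
    offset = offsets,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    basis = vapply(fits, `[[`, character(1), "basis"),
    stringsAsFactors = FALSE
  )
  list(matrix = setOmicsValues(x, centered), fits = fitdf)
}

#' Drop features observed in too few samples
#'
#' @param x An [OmicsMatrix-class].
#' @param minObs Minimum number of non-missing values a row must have to be
#'   retained (default 10, the cohort-wide observation filter).
#' @return The filtered [OmicsMatrix-class]; row order preserved. Dropped
#'   feature keys are kept in the `dropped` attribute.
#' @export
filterMinObserved <- function(x, minObs = 10L) {
  stopifnot(is(x, "OmicsMatrix"))
  v <- omicsValues(x)
  if (minObs < 1L || minObs > ncol(v))
    stop("minObs must be in [1, n_samples]")
  keep <- rowSums(!is.na(v)) >= minObs
  res <- setOmicsValues(x, v[keep, , drop = FALSE])
  attr(res, "dropped") <- rownames(v)[!keep]
  res
}

#' Re-reference CNV values to the cohort mean per gene
#'
#' Subtracts each gene's cohort mean so values become log-R ratios relative
#' to the cohort average for that gene.
#'
#' @param x An [OmicsMatrix-class] with level `cnv`.
#' @return The centered [OmicsMatrix-class].
#' @export
centerCnv <- function(x) {
  stopifnot(is(x, "OmicsMatrix"), omicsLevel(x) == "cnv")
  v <- omicsValues(x)
  setOmicsValues(x, v - rowMeans(v, na.rm = TRUE))
}
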