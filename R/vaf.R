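#' Pair somatic mutations between tumours and their xenografts
#'
#' Matches mutation calls on (gene, protein_change) between each tumour
#' sample and its paired PDX. Shared calls carry both VAFs; calls private
#' to one side are flagged. The retention summary counts, per pair, how
#' many of the tumour's calls were retained in the xenograft.
#'
#' @param tumour,pdx Mutation `data.frame`s as from [readMutations()].
#' @param pairing `data.frame` with columns `tumour_sample`,
#'   `pdx_sample` mapping each tumour sample to exactly one PDX.
#' @return List with `pairs` (one row per matched or private call:
#'   `tumour_sample`, `pdx_sample`, `gene`, `protein_change`,
#'   `tumour_vaf`, `pdx_vaf`, `status` in shared/tumour_only/pdx_only) and
#'   `retention` (per pair: shared, tumour_total, retention fraction).
#' @export
pairMutations <- function(tumour, pdx, pairing) {
  stopifnot(all(c("tumour_sample", "pdx_sample") %in% names(pairing)))
  if (anyDuplicated(pairing$tumour_sample))
    stop("pairing maps a tumour sample to multiple PDXs")
  unmapped <- c(setdiff(unique(tumour$sample), pairing$tumour_sample),
    setdiff(unique(pdx$sample), pairing$pdx_sample))
  if (length(unmapped))
    stop("samples missing from pairing: ",
      paste(unmapped, collapse = ", "))
  rows <- list(); ret <- list()
  for (i in seq_len(nrow(pairing))) {
    ts <- pairing$tumour_sample[i]
    ps <- pairing$pdx_sample[i]
    tm <- tumour[tumour$sample == ts, , drop = FALSE]
    pm <- pdx[pdx$sample == ps, , drop = FALSE]
    keyT <- paste(tm$gene, tm$protein_change)
    keyP <- paste(pm$gene, pm$protein_change)
    m <- match(keyT, keyP)
    shared <- !is.na(m)
    if (nrow(tm)) rows[[length(rows) + 1L]] <- data.frame(
      tumour_sample = ts, pdx_sample = ps, gene = tm$gene,
      protein_change = tm$protein_change, tumour_vaf = tm$vaf,
      pdx_vaf = ifelse(shared, pm$vaf[m], NA_real_),
      status = ifelse(shared, "shared", "tumour_only"),
      stringsAsFactors = FALSE)
    pdxOnly <- !(keyP %in% keyT)
    if (any(pdxOnly)) rows[[length(rows) + 1L]] <- data.frame(
      tumour_sample = ts, pdx_sample = ps, gene = pm$gene[pdxOnly],
      protein_change = pm$protein_change[pdxOnly],
      tumour_vaf = NA_real_, pdx_vaf = pm$vaf[pdxOnly],
      status = "pdx_only", stringsAsFactors = FALSE)
    ret[[length(ret) + 1L]] <- data.frame(
      tumour_sample = ts, pdx_sample = ps, shared = sum(shared),
      tumour_total = nrow(tm),
      retention = if (nrow(tm)) sum(shared) / nrow(tm) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(
    pairs = if (length(rows)) do.call(rbind, rows) else
      data.frame(tumour_sample = character(), pdx_sample = character(),
        gene = character(), protein_change = character(),
        tumour_vaf = numeric(), pdx_vaf = numeric(),
        status = character(), stringsAsFactors = FALSE),
    retention = do.call(rbind, ret))
}

#' VAF concordance between tumours and xenografts
#'
#' Pearson correlation of (tumour VAF, PDX VAF) over shared mutation
#' calls, pooled across pairs; raw fractions, untransformed.
#'
#' @param paired Output of [pairMutations()] (or its `pairs` element).
#' @return List with `r` (Pearson correlation, `NA` when not computable),
#'   `n` (number of shared calls used) and `computable`.
#' @export
vafConcordance <- function(paired) {
  pairs <- if (is.data.frame(paired)) paired else paired$pairs
  sh <- pairs[pairs$status == "shared" &
    !is.na(pairs$tumour_vaf) & !is.na(pairs$pdx_vaf), , drop = FALSE]
  n <- nrow(sh)
  if (n < 3L ||
      stats::sd(sh$tumour_vaf) == 0 || stats::sd(sh$pdx_vaf) == 0)
    return(list(r = NA_real_, n = n, computable = FALSE))
  list(r = stats::cor(sh$tumour_vaf, sh$pdx_vaf), n = n,
    computable = TRUE)
}
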