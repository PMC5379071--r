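#' Describe a synthetic multi-omic cohort
#'
#' Builds the sample sheet of a simulated xenograft study: a PDX discovery
#' cohort split into two intrinsic-subtype groups (basal-like and
#' luminal-like), optionally joined by a human tumour cohort processed in
#' the same experiment for co-clustering and outlier-validation analyses.
#' The default mirrors a 24-model PDX cohort (10 basal-like, 14
#' luminal-like); the human cohort defaults to 0 samples and is typically
#' set to 77 where needed.
#'
#' @param nBasal,nLuminal Number of basal-like / luminal-like PDX samples.
#' @param nHuman Number of human cohort samples (subtypes assigned in the
#'   same basal:luminal proportion).
#' @return A `data.frame` with columns `sample_id`, `subtype`
#'   (`basal`/`luminal`) and `cohort` (`pdx`/`human`).
#' @export
cohortDesign <- function(nBasal = 10L, nLuminal = 14L, nHuman = 0L) {
  stopifnot(nBasal >= 0, nLuminal >= 0, nBasal + nLuminal >= 2)
  pdx <- data.frame(
    sample_id = sprintf("PDX%02d", seq_len(nBasal + nLuminal)),
    subtype = rep(c("basal", "luminal"), c(nBasal, nLuminal)),
    cohort = "pdx", stringsAsFactors = FALSE)
  if (nHuman > 0L) {
    nb <- round(nHuman * nBasal / (nBasal + nLuminal))
    hum <- data.frame(
      sample_id = sprintf("HUM%02d", seq_len(nHuman)),
      subtype = rep(c("basal", "luminal"), c(nb, nHuman - nb)),
      cohort = "human", stringsAsFactors = FALSE)
    pdx <- rbind(pdx, hum)
  }
  pdx
}

#' Parameters for the synthetic cohort generator
#'
#' Returns the generation parameter set with defaults chosen to emulate an
#' isobaric-label PDX proteogenomics study: ~10,000 genes, protein and
#' phosphosite log-ratios with 20-60% per-feature missingness, an
#' mRNA-protein coupling distribution with median near the 0.536 observed
#' in such cohorts, per-sample loading offsets removed later by mixture
#' centering, subtype marker proteins, 1-5 phosphosites per gene tracking
#' the protein, and 12 paired tumour/PDX mutation sets whose VAF noise
#' yields a concordance near R = 0.66. Any default can be overridden by
#' name.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Named list of generation parameters.
#' @section Parameters:
#' \describe{
#'   \item{seed}{Integer RNG seed; the whole bundle is a deterministic
#'     function of (design, params).}
#'   \item{nGenes}{Number of genes (default 10000).}
#'   \item{mrnaSd, proteinSd, cnvSd, siteSd}{Base noise s.d. per layer on
#'     the log scale (defaults 1, 0.5, 0.3, 0.3). Planted outlier shifts
#'     are expressed in multiples of the layer s.d.}
#'   \item{geneEffectSdMrna, geneEffectSdProtein}{S.d. of per-gene baseline
#'     offsets (defaults 2, 0.3).}
#'   \item{loadingSd}{S.d. of the per-sample loading offset added to
#'     protein and phosphosite columns (default 0.2).}
#'   \item{coupling, couplingSd}{Target median and per-gene spread of the
#'     mRNA-protein correlation (defaults 0.536, 0.15).}
#'   \item{pathwayCoupling}{Named numeric vector of per-pathway coupling
#'     targets overriding the baseline for member genes (default none).}
#'   \item{nPathways, pathwaySizeRange}{Pathway collection shape (25 sets,
#'     20-80 genes).}
#'   \item{nDruggable}{Size of the simulated druggable-gene list (76).}
#'   \item{nSubtypeMarkers, subtypeShift}{Number of subtype marker genes
#'     and their between-subtype mean difference (200 genes, 1.5 log2
#'     units = 3x the protein noise s.d.).}
#'   \item{sitesPerGeneRange}{Range of phosphosites per gene (1-5).}
#'   \item{missingness}{Named list per level; scalar rate or
#'     `c(lo, hi)` range for per-feature rates. Defaults: cnv 0, mrna 0,
#'     protein and phosphosite 0.2-0.6.}
#'   \item{cohortShiftProp, cohortShiftSd}{Fraction of genes carrying a
#'     PDX-vs-human batch shift on the protein layer, and its s.d.
#'     (0.5, 0.8).}
#'   \item{outliers}{`data.frame(sample, gene, level, shift)` of planted
#'     single-sample expression outliers; shift in layer-s.d. units.
#'     Planted cells are exempt from missingness masking.}
#'   \item{activations}{`data.frame(sample, pathway, shift)` of planted
#'     per-sample pathway phospho-activations; shift in gene-level z-score
#'     units applied to all sites of member genes.}
#'   \item{nMutationPairs, mutationsPerPair}{Paired tumour/PDX mutation
#'     table shape (12 pairs, ~8 shared calls each).}
#'   \item{vafNoiseSd, vafBias}{PDX VAF = tumour VAF + bias + noise,
#'     clipped to (0, 1) (defaults 0.18, 0.03).}
#' }
#' @export
cohortParams <- function(...) {
  p <- list(
    seed = 1L,
    nGenes = 10000L,
    mrnaSd = 1.0, proteinSd = 0.5, cnvSd = 0.3, siteSd = 0.3,
    geneEffectSdMrna = 2.0, geneEffectSdProtein = 0.3,
    loadingSd = 0.2,
    coupling = 0.536, couplingSd = 0.15,
    pathwayCoupling = NULL,
    nPathways = 25L, pathwaySizeRange = c(20L, 80L),
    nDruggable = 76L,
    nSubtypeMarkers = 200L, subtypeShift = 1.5,
    sitesPerGeneRange = c(1L, 5L),
    missingness = list(cnv = 0, mrna = 0,
      protein = c(0.2, 0.6), phosphosite = c(0.2, 0.6)),
    cohortShiftProp = 0.5, cohortShiftSd = 0.8,
    outliers = NULL,
    activations = NULL,
    nMutationPairs = 12L, mutationsPerPair = 8L,
    vafNoiseSd = 0.18, vafBias = 0.03
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown))
    stop("unknown parameters: ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  for (lv in names(p$missingness)) {
    r <- p$missingness[[lv]]
    if (any(r < 0) || any(r >= 1))
      stop("missingness rate for ", lv, " outside [0, 1)")
  }
  p
}

.expandRate <- function(rate, n) {
  if (length(rate) == 2L) stats::runif(n, rate[1], rate[2]) else rep(rate, n)
}

#' Generate a synthetic multi-omic cohort with planted ground truth
#'
#' Draws a complete bundle of omic matrices with known structure. Per gene
#' g and sample s the mRNA and protein log values share a latent term
#' \eqn{Z_{gs}} with gene-specific mixing weight \eqn{w_g}:
#' \deqn{x_{gs} = \mu_g + m_{gs} + \sigma(\sqrt{w_g} Z_{gs} +
#'   \sqrt{1-w_g} E_{gs})}
#' so the mRNA-protein Pearson correlation of gene g is \eqn{w_g} by
#' construction; pathway-level coupling targets set \eqn{w_g} for member
#' genes. Subtype marker genes carry a between-subtype mean difference
#' \eqn{m_{gs}}, phosphosites track their gene's protein value plus site
#' noise, CNV is an independent log-R layer, and per-sample loading
#' offsets contaminate the protein/phosphosite columns. Planted
#' single-sample outlier shifts, per-sample pathway activations and paired
#' tumour/PDX mutation VAFs are recorded in the returned `truth`.
#'
#' @param design Sample sheet from [cohortDesign()].
#' @param params Parameter set from [cohortParams()].
#' @return A list (class `proteoCohort`) with elements `matrices` (named
#'   list of [OmicsMatrix-class]: `cnv`, `mrna`, `protein`, `phosphosite`),
#'   `mutations` (MAF-like `data.frame` for tumour and pdx cohorts),
#'   `geneSets` ([GeneSetCollection-class] of pathways), `druggable`
#'   (character vector), `truth` (planted ground truth), `design` and
#'   `params`.
#' @export
simulateCohort <- function(design, params = cohortParams()) {
  stopifnot(is.data.frame(design),
    all(c("sample_id", "subtype", "cohort") %in% names(design)))
  if (anyDuplicated(design$sample_id)) stop("duplicate sample ids")
  p <- params
  G <- p$nGenes
  samples <- design$sample_id
  S <- length(samples)
  genes <- sprintf("G%05d", seq_len(G))
  pathways <- sprintf("PW%02d", seq_len(p$nPathways))

  if (!is.null(p$pathwayCoupling)) {
    bad <- setdiff(names(p$pathwayCoupling), pathways)
    if (length(bad))
      stop("pathwayCoupling names not in pathway collection: ",
        paste(bad, collapse = ", "))
  }
  if (!is.null(p$outliers)) {
    o <- p$outliers
    stopifnot(all(c("sample", "gene", "level", "shift") %in% names(o)))
    if (!all(o$sample %in% samples))
      stop("planted outlier references unknown sample: ",
        paste(setdiff(o$sample, samples), collapse = ", "))
    if (!all(o$gene %in% genes))
      stop("planted outlier references unknown gene: ",
        paste(setdiff(o$gene, genes), collapse = ", "))
    if (!all(o$level %in% .OMICS_LEVELS))
      stop("planted outlier references unknown level")
    if (!all(is.finite(o$shift))) stop("outlier shifts must be finite")
  }
  if (!is.null(p$activations)) {
    a <- p$activations
    stopifnot(all(c("sample", "pathway", "shift") %in% names(a)))
    if (!all(a$sample %in% samples))
      stop("planted activation references unknown sample: ",
        paste(setdiff(a$sample, samples), collapse = ", "))
    if (!all(a$pathway %in% pathways))
      stop("planted activation references unknown pathway: ",
        paste(setdiff(a$pathway, pathways), collapse = ", "))
    if (!all(is.finite(a$shift))) stop("activation shifts must be finite")
  }

  set.seed(p$seed)

  # pathway membership and gene lists
  sizes <- sample(seq(p$pathwaySizeRange[1], p$pathwaySizeRange[2]),
    p$nPathways, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(genes, min(k, G)))
  names(sets) <- pathways
  druggable <- sample(genes, min(p$nDruggable, G))

  # per-gene structure
  muM <- stats::rnorm(G, 0, p$geneEffectSdMrna)
  muP <- stats::rnorm(G, 0, p$geneEffectSdProtein)
  w <- stats::rnorm(G, p$coupling, p$couplingSd)
  names(w) <- genes
  if (!is.null(p$pathwayCoupling)) {
    for (pw in names(p$pathwayCoupling))
      w[sets[[pw]]] <- p$pathwayCoupling[[pw]]
  }
  w <- pmin(pmax(w, 0.02), 0.95)

  markerIdx <- sample(G, min(p$nSubtypeMarkers, G))
  markerSign <- sample(c(-1, 1), length(markerIdx), replace = TRUE)
  markerEffect <- matrix(0, G, S)
  basal <- design$subtype == "basal"
  markerEffect[markerIdx, basal] <- markerSign * p$subtypeShift

  # latent + noise draws
  Z <- matrix(stats::rnorm(G * S), G, S)
  E1 <- matrix(stats::rnorm(G * S), G, S)
  E2 <- matrix(stats::rnorm(G * S), G, S)
  E3 <- matrix(stats::rnorm(G * S), G, S)
  sw <- sqrt(w); cw <- sqrt(1 - w)

  mrna <- muM + markerEffect + p$mrnaSd * (sw * Z + cw * E1)
  proteinSignal <- muP + markerEffect + p$proteinSd * (sw * Z + cw * E2)
  loading <- stats::rnorm(S, 0, p$loadingSd)
  cohortShiftGene <- ifelse(
    stats::runif(G) < p$cohortShiftProp,
    stats::rnorm(G, 0, p$cohortShiftSd), 0)
  isHuman <- design$cohort == "human"
  protein <- proteinSignal +
    outer(cohortShiftGene, as.numeric(isHuman)) +
    matrix(loading, G, S, byrow = TRUE)
  cnv <- p$cnvSd * E3
  dimnames(mrna) <- dimnames(protein) <- dimnames(cnv) <-
    list(genes, samples)

  # phosphosites track the protein signal
  nSites <- sample(seq(p$sitesPerGeneRange[1], p$sitesPerGeneRange[2]),
    G, replace = TRUE)
  siteGene <- rep(seq_len(G), nSites)
  nSiteRows <- length(siteGene)
  residue <- sample(c("S", "T", "Y"), nSiteRows, replace = TRUE,
    prob = c(0.7, 0.2, 0.1))
  position <- sample(30:1500, nSiteRows, replace = TRUE)
  siteKeys <- sprintf("%s:%s%d", genes[siteGene], residue, position)
  # keys must be unique within a gene
  while (anyDuplicated(siteKeys)) {
    d <- duplicated(siteKeys)
    position[d] <- sample(30:1500, sum(d), replace = TRUE)
    siteKeys <- sprintf("%s:%s%d", genes[siteGene], residue, position)
  }
  siteEff <- stats::rnorm(nSiteRows, 0, 0.3)
  phosLoading <- stats::rnorm(S, 0, p$loadingSd)
  phospho <- proteinSignal[siteGene, , drop = FALSE] + siteEff +
    p$siteSd * matrix(stats::rnorm(nSiteRows * S), nSiteRows, S) +
    matrix(phosLoading, nSiteRows, S, byrow = TRUE)
  dimnames(phospho) <- list(siteKeys, samples)

  # planted activations: shift all sites of member genes, in units of the
  # gene-level (site-averaged) cross-sample s.d.
  truthAct <- data.frame(sample = character(), pathway = character(),
    shift = numeric(), stringsAsFactors = FALSE)
  if (!is.null(p$activations) && nrow(p$activations)) {
    geneSdLevel <- sqrt(p$proteinSd^2 + p$siteSd^2 / nSites)
    for (i in seq_len(nrow(p$activations))) {
      a <- p$activations[i, ]
      memb <- which(genes[siteGene] %in% sets[[a$pathway]])
      sj <- match(a$sample, samples)
      phospho[memb, sj] <- phospho[memb, sj] +
        a$shift * geneSdLevel[siteGene[memb]]
    }
    truthAct <- p$activations[, c("sample", "pathway", "shift")]
  }

  # planted single-sample expression outliers, in layer-s.d. units
  layerSd <- c(cnv = p$cnvSd, mrna = p$mrnaSd, protein = p$proteinSd,
    phosphosite = sqrt(p$proteinSd^2 + p$siteSd^2))
  truthOut <- data.frame(sample = character(), gene = character(),
    level = character(), shift = numeric(), stringsAsFactors = FALSE)
  plantedCells <- list(cnv = NULL, mrna = NULL, protein = NULL,
    phosphosite = NULL)
  if (!is.null(p$outliers) && nrow(p$outliers)) {
    for (i in seq_len(nrow(p$outliers))) {
      o <- p$outliers[i, ]
      sj <- match(o$sample, samples)
      delta <- o$shift * layerSd[[o$level]]
      if (o$level == "phosphosite") {
        rows <- which(siteGene == match(o$gene, genes))
        phospho[rows, sj] <- phospho[rows, sj] + delta
        plantedCells$phosphosite <- rbind(plantedCells$phosphosite,
          cbind(rows, sj))
      } else {
        gi <- match(o$gene, genes)
        m <- switch(o$level, cnv = "cnv", mrna = "mrna",
          protein = "protein")
        if (m == "cnv") cnv[gi, sj] <- cnv[gi, sj] + delta
        if (m == "mrna") mrna[gi, sj] <- mrna[gi, sj] + delta
        if (m == "protein") protein[gi, sj] <- protein[gi, sj] + delta
        plantedCells[[m]] <- rbind(plantedCells[[m]], cbind(gi, sj))
      }
    }
    truthOut <- p$outliers[, c("sample", "gene", "level", "shift")]
  }

  # missing-completely-at-random masking per level (planted cells exempt)
  maskLevel <- function(mat, rate, keep) {
    rates <- .expandRate(rate, nrow(mat))
    mask <- matrix(stats::runif(length(mat)), nrow(mat)) <
      matrix(rates, nrow(mat), ncol(mat))
    if (!is.null(keep)) mask[keep] <- FALSE
    mat[mask] <- NA_real_
    mat
  }
  cnv <- maskLevel(cnv, p$missingness$cnv, plantedCells$cnv)
  mrna <- maskLevel(mrna, p$missingness$mrna, plantedCells$mrna)
  protein <- maskLevel(protein, p$missingness$protein,
    plantedCells$protein)
  phospho <- maskLevel(phospho, p$missingness$phosphosite,
    plantedCells$phosphosite)

  # paired tumour/PDX mutation tables
  pdxIds <- design$sample_id[design$cohort == "pdx"]
  nPairs <- min(p$nMutationPairs, length(pdxIds))
  mut <- list(); vafPairs <- list()
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
    "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in seq_len(nPairs)) {
    pdxId <- pdxIds[i]
    tumId <- sprintf("TUM%02d", i)
    nShared <- max(1L, stats::rpois(1, p$mutationsPerPair))
    nTumOnly <- stats::rpois(1, 2)
    nPdxOnly <- stats::rpois(1, 1)
    k <- nShared + nTumOnly + nPdxOnly
    mg <- sample(c(sample(druggable, min(2, k)),
      sample(genes, max(0, k - 2))), k)
    pc <- sprintf("p.%s%d%s", sample(aa, k, TRUE),
      sample(30:1200, k, TRUE), sample(aa, k, TRUE))
    tv <- stats::runif(k, 0.05, 0.6)
    pv <- pmin(pmax(tv + p$vafBias +
      stats::rnorm(k, 0, p$vafNoiseSd), 0.01), 0.99)
    isShared <- seq_len(k) <= nShared
    isTum <- seq_len(k) <= nShared + nTumOnly
    mut[[length(mut) + 1L]] <- rbind(
      data.frame(sample = tumId, gene = mg[isTum],
        protein_change = pc[isTum], vaf = tv[isTum], cohort = "tumour",
        stringsAsFactors = FALSE),
      data.frame(sample = pdxId, gene = mg[isShared | !isTum],
        protein_change = pc[isShared | !isTum],
        vaf = pv[isShared | !isTum], cohort = "pdx",
        stringsAsFactors = FALSE))
    vafPairs[[length(vafPairs) + 1L]] <- data.frame(
      tumour_sample = tumId, pdx_sample = pdxId, gene = mg[isShared],
      protein_change = pc[isShared], tumour_vaf = tv[isShared],
      pdx_vaf = pv[isShared], stringsAsFactors = FALSE)
  }
  mutations <- if (length(mut)) do.call(rbind, mut) else
    data.frame(sample = character(), gene = character(),
      protein_change = character(), vaf = numeric(),
      cohort = character(), stringsAsFactors = FALSE)
  vafTruth <- if (length(vafPairs)) do.call(rbind, vafPairs) else NULL

  truth <- list(
    outliers = truthOut,
    activations = truthAct,
    subtypeMarkers = data.frame(gene = genes[markerIdx],
      sign = markerSign,
      shift = rep(p$subtypeShift, length(markerIdx)),
      stringsAsFactors = FALSE),
    coupling = list(target = p$coupling,
      pathwayCoupling = as.list(p$pathwayCoupling)),
    vafPairs = vafTruth
  )

  structure(list(
    matrices = list(
      cnv = OmicsMatrix(cnv, "cnv"),
      mrna = OmicsMatrix(mrna, "mrna"),
      protein = OmicsMatrix(protein, "protein"),
      phosphosite = OmicsMatrix(phospho, "phosphosite")),
    mutations = mutations,
    geneSets = GeneSetCollection(sets),
    druggable = druggable,
    truth = truth,
    design = design,
    params = p
  ), class = "proteoCohort")
}

#' @export
print.proteoCohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic multi-omic cohort: %d samples (%d pdx, %d human), %d genes\n",
    nrow(x$design), sum(x$design$cohort == "pdx"),
    sum(x$design$cohort == "human"), x$params$nGenes))
  invisible(x)
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits one TSV per omic matrix, a GMT of the pathway collection, the
#' druggable-gene list, the MAF-like mutation table, the sample sheet and
#' a JSON truth manifest of the planted events. Files round-trip
#' losslessly through [readOmicsMatrix()], [readGmt()], [readMutations()]
#' and [readGeneList()].
#'
#' @param bundle A cohort from [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
writeCohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "proteoCohort"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  paths <- c(
    cnv = file.path(dir, "cnv.tsv"),
    mrna = file.path(dir, "mrna.tsv"),
    protein = file.path(dir, "protein.tsv"),
    phosphosite = file.path(dir, "phosphosite.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    druggable = file.path(dir, "druggable.txt"),
    mutations = file.path(dir, "mutations.tsv"),
    design = file.path(dir, "design.tsv"),
    pairing = file.path(dir, "pairing.tsv"),
    truth = file.path(dir, "truth.json"))
  for (lv in names(bundle$matrices))
    writeOmicsMatrix(bundle$matrices[[lv]], paths[[lv]])
  writeGmt(bundle$geneSets, paths[["pathways"]])
  writeLines(bundle$druggable, paths[["druggable"]])
  writeMutations(bundle$mutations, paths[["mutations"]])
  utils::write.table(bundle$design, paths[["design"]], sep = "\t",
    quote = FALSE, row.names = FALSE)
  vp <- bundle$truth$vafPairs
  pairing <- if (!is.null(vp))
    unique(vp[, c("tumour_sample", "pdx_sample")]) else
    data.frame(tumour_sample = character(), pdx_sample = character())
  utils::write.table(pairing, paths[["pairing"]], sep = "\t",
    quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, paths[["truth"]],
    auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  invisible(paths)
}

#' Read back a truth manifest written by [writeCohort()]
#'
#' @param path Path to `truth.json`.
#' @return List of planted-event tables.
#' @export
readCohortTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
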