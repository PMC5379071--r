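#' Default pipeline configuration
#'
#' Returns the run configuration skeleton for [runPipeline()]. `inputs`
#' are file paths as written by [writeCohort()] (any may be `NULL` to
#' skip dependent stages); `stages` toggles each analysis; `params` holds
#' the per-stage tuning knobs with the study-standard defaults (10-sample
#' observation filter, 30% correlation coverage, 2 / 2.5 s.d. marker
#' thresholds for proteome / phosphoproteome, k = 2 clusters, activation
#' FDR 0.01, co-clustering FDR floor 0.3).
#'
#' @param ... Named overrides applied on top of the defaults (nested
#'   lists are replaced wholesale).
#' @return Nested configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    out_dir = "proteopdx-run",
    inputs = list(cnv = NULL, mrna = NULL, protein = NULL,
      phosphosite = NULL, mutations = NULL, pathways = NULL,
      druggable = NULL, design = NULL, pairing = NULL),
    stages = list(normalize = TRUE, correlation = TRUE,
      clustering = TRUE, diffexp = TRUE, outliers = TRUE,
      phospho = TRUE, vaf = TRUE, human_validation = TRUE),
    params = list(min_obs = 10L, min_frac = 0.30,
      sd_protein = 2, sd_phospho = 2.5, k = 2L,
      fdr_activation = 0.01, fdr_floor = 0.3,
      score_threshold = 1.5, cross_threshold = 1)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% names(cfg) && is.list(cfg[[nm]]) && is.list(ov[[nm]])) {
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      cfg[[nm]] <- ov[[nm]]
    }
  }
  cfg
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  path
}

#' Run the full proteogenomic analysis pipeline
#'
#' Executes the enabled stages in dependency order — ingest, mixture
#' re-centering and observation filtering, mRNA-protein correlation with
#' pathway enrichment, proteomic/phosphoproteomic subtyping, subtype
#' differential expression with gene-set enrichment, druggable outlier
#' calling (with human-cohort validation when human samples are present),
#' phosphoproteomic pathway activation, and tumour/PDX VAF concordance —
#' writing each stage's tables under `out_dir` plus a JSON run manifest
#' (package version, parameters, per-stage status and row counts).
#' Outputs are a pure function of config + inputs: a rerun writes
#' byte-identical files. A stage failure stops the run with the stage
#' named and a `FAILED` marker recorded in the manifest.
#'
#' @param config Configuration list from [pipelineConfig()], or the path
#'   to a YAML file holding one.
#' @return Invisibly, a list of in-memory stage results plus the
#'   manifest.
#' @export
runPipeline <- function(config) {
  if (is.character(config))
    config <- do.call(pipelineConfig, yaml::read_yaml(config))
  cfg <- config
  p <- cfg$params
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "ProteoPDX",
    version = as.character(utils::packageVersion("ProteoPDX")),
    params = p, stages = list())
  results <- list()
  note <- function(stage, status, rows = NULL, files = NULL) {
    manifest$stages[[stage]] <<- list(status = status,
      rows = rows, files = files)
  }
  runStage <- function(stage, enabled, fun) {
    if (!enabled) {
      note(stage, "SKIPPED")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      note(stage, "FAILED")
      writeLines(c(stage, conditionMessage(res)),
        file.path(cfg$out_dir, "FAILED"))
      jsonlite::write_json(manifest,
        file.path(cfg$out_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, null = "null")
      stop("stage '", stage, "' failed: ", conditionMessage(res),
        call. = FALSE)
    }
    results[[stage]] <<- res
    invisible(res)
  }
  # ingest
  runStage("ingest", TRUE, function() {
    inp <- cfg$inputs
    mats <- list()
    for (lv in c("cnv", "mrna", "protein", "phosphosite"))
      if (!is.null(inp[[lv]]))
        mats[[lv]] <- readOmicsMatrix(inp[[lv]], lv)
    design <- if (!is.null(inp$design))
      utils::read.delim(inp$design, stringsAsFactors = FALSE) else NULL
    list(matrices = mats, design = design,
      mutations = if (!is.null(inp$mutations))
        readMutations(inp$mutations) else NULL,
      pathways = if (!is.null(inp$pathways))
        readGmt(inp$pathways) else NULL,
      druggable = if (!is.null(inp$druggable))
        readGeneList(inp$druggable) else NULL,
      pairing = if (!is.null(inp$pairing))
        utils::read.delim(inp$pairing, stringsAsFactors = FALSE)
        else NULL)
  })
  note("ingest", "OK",
    rows = lapply(results$ingest$matrices, nrow))
  ing <- results$ingest
  design <- ing$design
  pdxIds <- if (!is.null(design))
    design$sample_id[design$cohort == "pdx"] else NULL
  humIds <- if (!is.null(design))
    design$sample_id[design$cohort == "human"] else character()

  # normalize: mixture-center ratio levels, observation filter, gene
  # collapse; CNV assumed already log-R transformed
  runStage("normalize", isTRUE(cfg$stages$normalize), function() {
    mats <- ing$matrices
    fits <- list()
    for (lv in intersect(c("protein", "phosphosite"), names(mats))) {
      mc <- mixtureCenter(mats[[lv]])
      mats[[lv]] <- mc$matrix
      fits[[lv]] <- mc$fits
      .writeTsv(mc$fits,
        file.path(cfg$out_dir, paste0("mixture_fits_", lv, ".tsv")))
    }
    for (lv in names(mats))
      mats[[lv]] <- filterMinObserved(mats[[lv]], p$min_obs)
    for (lv in intersect(c("mrna", "protein"), names(mats)))
      mats[[lv]] <- collapseToGene(mats[[lv]])
    list(matrices = mats, fits = fits)
  })
  mats <- if (!is.null(results$normalize))
    results$normalize$matrices else ing$matrices
  if (!is.null(results$normalize))
    note("normalize", "OK", rows = lapply(mats, nrow))
  sub <- function(m, ids) {
    if (is.null(ids) || !length(ids)) return(NULL)
    OmicsMatrix(omicsValues(m)[, intersect(colnames(m), ids),
      drop = FALSE], omicsLevel(m))
  }
  pdxMats <- lapply(mats, function(m)
    if (is.null(pdxIds)) m else sub(m, pdxIds))
  humMats <- if (length(humIds))
    lapply(mats, sub, ids = humIds) else NULL

  # mRNA-protein correlation + KS pathway enrichment
  runStage("correlation",
    isTRUE(cfg$stages$correlation) &&
      all(c("mrna", "protein") %in% names(mats)) &&
      !is.null(ing$pathways),
    function() {
      cors <- geneCorrelation(pdxMats$mrna, pdxMats$protein,
        minFrac = p$min_frac)
      enr <- ksPathwayEnrichment(cors, ing$pathways)
      .writeTsv(cors, file.path(cfg$out_dir, "gene_correlations.tsv"))
      .writeTsv(enr, file.path(cfg$out_dir,
        "correlation_enrichment.tsv"))
      list(correlations = cors, enrichment = enr)
    })
  if (!is.null(results$correlation))
    note("correlation", "OK",
      rows = list(genes = nrow(results$correlation$correlations),
        sets = nrow(results$correlation$enrichment)))

  # proteomic subtyping
  runStage("clustering",
    isTRUE(cfg$stages$clustering) && "protein" %in% names(mats),
    function() {
      mk <- selectVariableMarkers(pdxMats$protein, p$sd_protein,
        p$min_obs)
      if (length(mk) < 2L)
        return(list(markers = mk, clustering = NULL))
      cl <- clusterSamples(pdxMats$protein, markers = mk, k = p$k)
      .writeTsv(data.frame(sample = names(cl$labels),
        cluster = cl$labels), file.path(cfg$out_dir,
        "protein_clusters.tsv"))
      exportNewick(cl, file.path(cfg$out_dir, "protein_dendrogram.nwk"))
      list(markers = mk, clustering = cl)
    })
  if (!is.null(results$clustering))
    note("clustering",
      if (is.null(results$clustering$clustering))
        "OK (no markers passed the s.d. filter)" else "OK",
      rows = list(markers = length(results$clustering$markers)))

  # subtype differential expression + gene-set enrichment
  runStage("diffexp",
    isTRUE(cfg$stages$diffexp) && "protein" %in% names(mats) &&
      !is.null(design) && !is.null(ing$pathways),
    function() {
      groups <- stats::setNames(design$subtype, design$sample_id)
      groups <- groups[colnames(pdxMats$protein)]
      de <- differentialTest(pdxMats$protein, groups)
      enr <- rankedGeneSetEnrichment(de, ing$pathways)
      .writeTsv(de, file.path(cfg$out_dir,
        "differential_expression.tsv"))
      .writeTsv(enr, file.path(cfg$out_dir, "diffexp_enrichment.tsv"))
      list(differential = de, enrichment = enr)
    })
  if (!is.null(results$diffexp))
    note("diffexp", "OK",
      rows = list(features = nrow(results$diffexp$differential)))

  # druggable outliers (+ human validation)
  runStage("outliers",
    isTRUE(cfg$stages$outliers) && !is.null(ing$druggable),
    function() {
      calls <- suppressWarnings(callOutliers(
        Filter(Negate(is.null), pdxMats), ing$druggable,
        minObs = p$min_obs, scoreThreshold = p$score_threshold,
        crossThreshold = p$cross_threshold))
      .writeTsv(calls, file.path(cfg$out_dir, "outlier_calls.tsv"))
      top <- calls[calls$is_outlier & calls$rank <= 3, , drop = FALSE]
      .writeTsv(top, file.path(cfg$out_dir, "top_outliers.tsv"))
      census <- if (!is.null(ing$mutations))
        druggableMutationCensus(
          ing$mutations[ing$mutations$cohort == "pdx", , drop = FALSE],
          ing$druggable, cohortSize = length(pdxIds)) else NULL
      list(calls = calls, census = census)
    })
  if (!is.null(results$outliers))
    note("outliers", "OK",
      rows = list(calls = nrow(results$outliers$calls),
        outliers = sum(results$outliers$calls$is_outlier)))

  runStage("human_validation",
    isTRUE(cfg$stages$human_validation) &&
      !is.null(results$outliers) && !is.null(humMats),
    function() {
      hv <- humanValidation(results$outliers$calls,
        Filter(Negate(is.null), humMats), ing$druggable,
        minObs = p$min_obs)
      .writeTsv(hv$calls, file.path(cfg$out_dir,
        "human_validated_outliers.tsv"))
      hv
    })
  note("human_validation",
    if (is.null(results$human_validation)) "SKIPPED" else "OK",
    rows = if (!is.null(results$human_validation))
      list(calls = nrow(results$human_validation$calls)))

  # phosphoproteomic pathway activation
  runStage("phospho",
    isTRUE(cfg$stages$phospho) && "phosphosite" %in% names(mats) &&
      !is.null(ing$pathways),
    function() {
      genePhos <- collapsePhosphoToGene(pdxMats$phosphosite)
      z <- modifiedZscore(genePhos, minObs = p$min_obs)
      act <- pathwayActivation(z, ing$pathways,
        fdr = p$fdr_activation)
      .writeTsv(act, file.path(cfg$out_dir, "pathway_activation.tsv"))
      list(zscores = z, activation = act)
    })
  if (!is.null(results$phospho))
    note("phospho", "OK",
      rows = list(tests = nrow(results$phospho$activation),
        activated = sum(results$phospho$activation$activated)))

  # tumour/PDX VAF concordance
  runStage("vaf",
    isTRUE(cfg$stages$vaf) && !is.null(ing$mutations) &&
      !is.null(ing$pairing),
    function() {
      mut <- ing$mutations
      paired <- pairMutations(
        mut[mut$cohort == "tumour", , drop = FALSE],
        mut[mut$cohort == "pdx", , drop = FALSE], ing$pairing)
      conc <- vafConcordance(paired)
      .writeTsv(paired$pairs, file.path(cfg$out_dir,
        "vaf_pairs.tsv"))
      .writeTsv(paired$retention, file.path(cfg$out_dir,
        "vaf_retention.tsv"))
      list(paired = paired, concordance = conc)
    })
  note("vaf",
    if (is.null(results$vaf)) "SKIPPED" else "OK",
    rows = if (!is.null(results$vaf))
      list(shared = results$vaf$concordance$n))

  jsonlite::write_json(manifest,
    file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}
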