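test_that("outlier scores follow the quartile convention exactly", {
  sc <- outlierScore(c(1, 2, 3, 4, 100))
  expect_equal(sc$q1, 2)  # h = (n-1)p interpolation
  expect_equal(sc$q3, 4)
  expect_equal(sc$iqr, 2)
  expect_equal(sc$score[5], 48)
  expect_equal(sc$score[4], 0)
  expect_true(sc$score[5] > 1.5 && sc$score[4] <= 1.5)
  expect_equal(sc$q1, quantileBrute(c(1, 2, 3, 4, 100), 0.25))
  expect_equal(sc$q3, quantileBrute(c(1, 2, 3, 4, 100), 0.75))
})

test_that("degenerate spreads are handled by the definition, not NaN", {
  flat <- outlierScore(rep(2, 8))
  expect_true(all(flat$score == 0))
  spike <- outlierScore(c(1, 1, 1, 1, 5))
  expect_identical(spike$iqr, 0)
  expect_identical(spike$score[5], Inf)
  expect_true(all(spike$score[1:4] == 0))
  withNA <- outlierScore(c(1, NA, 2, 3, 4, 100))
  expect_true(is.na(withNA$score[2]))
})

test_that("score threshold and direct fence test are the same rule", {
  set.seed(91)
  for (i in 1:200) {
    x <- rnorm(24)
    sc <- outlierScore(x)
    expect_identical(sc$score > 1.5, fenceBrute(x))
  }
})

test_that("scores are monotone in the value and shift-invariant", {
  set.seed(92)
  x <- rnorm(24)
  s0 <- outlierScore(x)$score
  expect_equal(outlierScore(x + 7)$score, s0, tolerance = 1e-12)
  for (i in 1:20) {
    j <- sample(24, 1)
    x2 <- x
    x2[j] <- x2[j] + runif(1, 0, 3)
    expect_gte(outlierScore(x2)$score[j], s0[j])
  }
})

mkLevel <- function(v, level) {
  OmicsMatrix(v, level)
}

test_that("calls are druggable-restricted, ranked, and CNV cross-validated", {
  set.seed(93)
  n <- 12
  samples <- sprintf("s%02d", 1:n)
  base <- matrix(rnorm(5 * n, sd = 0.2), 5, n,
    dimnames = list(c("DRG1", "DRG2", "DRG3", "OTHER", "DRG4"), samples))
  cnv <- base
  cnv["DRG1", "s01"] <- 5    # CNV outlier without expression support
  cnv["DRG2", "s02"] <- 5    # CNV outlier with mRNA support
  mrna <- base
  mrna["DRG2", "s02"] <- 6
  prot <- base
  prot["DRG3", "s03"] <- 4   # two outliers in one sample, ordered
  prot["DRG4", "s03"] <- 8
  druggable <- c("DRG1", "DRG2", "DRG3", "DRG4", "ABSENT")
  expect_warning(
    calls <- callOutliers(list(
      cnv = mkLevel(cnv, "cnv"), mrna = mkLevel(mrna, "mrna"),
      protein = mkLevel(prot, "protein")), druggable, minObs = 10),
    "ABSENT")
  expect_false("OTHER" %in% calls$gene)
  c1 <- calls[calls$level == "cnv" & calls$sample == "s01" &
    calls$gene == "DRG1", ]
  expect_true(c1$is_outlier)
  expect_false(c1$cnv_cross_validated)
  c2 <- calls[calls$level == "cnv" & calls$sample == "s02" &
    calls$gene == "DRG2", ]
  expect_true(c2$cnv_cross_validated)
  p3 <- calls[calls$level == "protein" & calls$sample == "s03", ]
  expect_identical(p3$gene[p3$rank == 1], "DRG4")
  expect_identical(p3$gene[p3$rank == 2], "DRG3")
  expect_false(any(duplicated(
    calls[c("level", "sample", "rank")])))
})

test_that("cross-validation needs a strict score above 1", {
  n <- 12
  samples <- sprintf("s%02d", 1:n)
  v0 <- matrix(rep(seq(0, 1.1, length.out = n), each = 2), 2, n,
    dimnames = list(c("DRG1", "DRG2"), samples))
  cnv <- v0; cnv["DRG1", "s12"] <- 30
  # mRNA value at the top of the cohort but score below 1
  mrna <- v0
  calls <- callOutliers(list(cnv = mkLevel(cnv, "cnv"),
    mrna = mkLevel(mrna, "mrna")), c("DRG1", "DRG2"), minObs = 10)
  mr <- calls[calls$level == "mrna" & calls$sample == "s12" &
    calls$gene == "DRG1", ]
  expect_lte(mr$score, 1)
  cc <- calls[calls$level == "cnv" & calls$sample == "s12" &
    calls$gene == "DRG1", ]
  expect_true(cc$is_outlier)
  expect_false(cc$cnv_cross_validated)
})

test_that("phosphosites inherit druggability from their gene", {
  set.seed(94)
  v <- matrix(rnorm(36, sd = 0.3), 3, 12, dimnames = list(
    c("DRG1:S473", "DRG1:T308", "OTHER:S15"), sprintf("s%02d", 1:12)))
  v["DRG1:S473", "s05"] <- 4
  calls <- callOutliers(list(phosphosite = mkLevel(v, "phosphosite")),
    "DRG1", minObs = 10)
  expect_setequal(unique(calls$gene), "DRG1")
  top <- calls[calls$sample == "s05" & calls$rank == 1, ]
  expect_identical(top$feature, "DRG1:S473")
  expect_true(top$is_outlier)
})

test_that("planted protein outliers surface at rank 1 in their sample", {
  d <- cohortDesign(10, 14)
  pre <- simulateCohort(d, cohortParams(nGenes = 300, seed = 23))
  gene <- pre$druggable[1]
  b <- simulateCohort(d, cohortParams(nGenes = 300, seed = 23,
    outliers = data.frame(sample = "PDX07", gene = gene,
      level = "protein", shift = 6, stringsAsFactors = FALSE)))
  calls <- suppressWarnings(callOutliers(
    list(protein = b$matrices$protein), b$druggable))
  hit <- calls[calls$sample == "PDX07" & calls$gene == gene, ]
  expect_true(hit$is_outlier)
  expect_identical(as.integer(hit$rank), 1L)
})

test_that("human validation applies both the score and top-rank criteria", {
  set.seed(95)
  n <- 12
  samples <- sprintf("h%02d", 1:n)
  spread <- seq(-1, 1, length.out = n)
  # 40 noise features so that mid-pack genes are never in a sample's
  # top 2; their h12 value sits at the row median (negative score)
  # so the h12 top-2 is deterministic. NEITHER is flat (all scores 0).
  vh <- matrix(rnorm(40 * n), 40, n,
    dimnames = list(sprintf("NOISE%02d", 1:40), samples))
  vh[, "h12"] <- apply(vh[, 1:(n - 1)], 1, median)
  vh <- rbind(vh, SCORED = spread, TOPPED = spread,
    NEITHER = rep(0.5, n))
  # SCORED: h12 pushed far out (score > 1); TOPPED: below the score
  # floor everywhere but second-largest score in h12
  vh["SCORED", "h12"] <- 10
  vh["TOPPED", "h12"] <- 1.45
  hScores <- apply(vh, 1, function(r) outlierScore(r)$score)
  expect_lte(max(hScores[, "TOPPED"]), 1)
  expect_identical(
    rownames(vh)[order(hScores["h12", ], decreasing = TRUE)[1:2]],
    c("SCORED", "TOPPED"))
  pdxCalls <- data.frame(
    sample = "PDX01",
    feature = c("SCORED", "TOPPED", "NEITHER", "GONE"),
    gene = c("SCORED", "TOPPED", "NEITHER", "GONE"),
    level = "protein", value = 5, q1 = 0, q3 = 1, iqr = 1,
    score = 4, rank = 1:4, is_outlier = TRUE,
    cnv_cross_validated = NA, stringsAsFactors = FALSE)
  hv <- humanValidation(pdxCalls,
    list(protein = mkLevel(vh, "protein")),
    druggable = rownames(vh), minObs = 10)
  got <- setNames(hv$calls$human_validated, hv$calls$feature)
  expect_true(got[["SCORED"]])   # via score > 1
  expect_true(got[["TOPPED"]])   # via per-sample top-2 rank only
  expect_false(got[["NEITHER"]]) # neither criterion fires
  expect_false(hv$calls$assessable[hv$calls$feature == "GONE"])
  expect_equal(hv$rates[["protein"]], 2 / 3)
  # with the rank criterion disabled, TOPPED is no longer validated
  hv2 <- humanValidation(pdxCalls,
    list(protein = mkLevel(vh, "protein")),
    druggable = rownames(vh), minObs = 10, topK = 0)
  got2 <- setNames(hv2$calls$human_validated, hv2$calls$feature)
  expect_true(got2[["SCORED"]])
  expect_false(got2[["TOPPED"]])
})

test_that("the druggable mutation census counts distinct samples once", {
  mut <- data.frame(
    sample = c("S1", "S1", "S2", "S3"),
    gene = c("PIK3CA", "KRAS", "PIK3CA", "TTN"),
    protein_change = c("p.H1047R", "p.A146V", "p.E545K", "p.X1Y"),
    vaf = c(0.3, 0.2, 0.4, 0.1), cohort = "pdx",
    stringsAsFactors = FALSE)
  cz <- druggableMutationCensus(mut, c("PIK3CA", "KRAS"))
  expect_identical(cz$nSamples, 2L)
  expect_identical(nrow(cz$bySample[["S1"]]), 2L)
  expect_identical(druggableMutationCensus(mut,
    character(0))$nSamples, 0L)
  expect_equal(druggableMutationCensus(mut, "PIK3CA",
    cohortSize = 24)$fraction, 2 / 24)
})
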