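test_that("marker selection orders by descending s.d. above the cutoff", {
  set.seed(6)
  base <- rnorm(20)
  v <- rbind(
    A = base / sd(base) * 2.6,
    B = base / sd(base) * 1.9,
    C = base / sd(base) * 2.1,
    K = rep(3, 20))
  colnames(v) <- sprintf("s%02d", 1:20)
  mk <- selectVariableMarkers(OmicsMatrix(v, "protein"),
    sdThreshold = 2)
  expect_identical(as.character(mk), c("A", "C"))
  expect_equal(attr(mk, "sd"), c(2.6, 2.1), tolerance = 1e-12)
  # constant rows can never be selected
  expect_false("K" %in% mk)
})

test_that("marker selection is monotone in the s.d. threshold", {
  set.seed(16)
  v <- matrix(rnorm(30 * 20, sd = rep(runif(30, 0.5, 3), 20)), 30, 20,
    dimnames = list(sprintf("F%02d", 1:30), sprintf("s%02d", 1:20)))
  m <- OmicsMatrix(v, "protein")
  prev <- selectVariableMarkers(m, 0.5)
  for (th in c(1, 1.5, 2, 2.5)) {
    cur <- selectVariableMarkers(m, th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("duplicate samples merge first at height zero", {
  set.seed(26)
  v <- matrix(rnorm(40), 10, 4,
    dimnames = list(sprintf("F%02d", 1:10), c("a", "b", "c", "d")))
  v[, "b"] <- v[, "a"]
  cl <- clusterSamples(OmicsMatrix(v, "protein"), k = 2)
  expect_equal(min(cl$tree$height), 0)
  first <- cl$tree$merge[1, ]
  expect_setequal(cl$tree$labels[-first], c("a", "b"))
})

test_that("sample order does not change the tree topology", {
  set.seed(36)
  v <- matrix(rnorm(200), 20, 10,
    dimnames = list(sprintf("F%02d", 1:20), sprintf("s%02d", 1:10)))
  m1 <- OmicsMatrix(v, "protein")
  perm <- sample(10)
  m2 <- OmicsMatrix(v[, perm], "protein")
  cl1 <- clusterSamples(m1, k = 3)
  cl2 <- clusterSamples(m2, k = 3)
  expect_equal(sort(cl1$tree$height), sort(cl2$tree$height))
  # same partition up to label permutation
  skip_if_not_installed("mclust")
  common <- sort(colnames(v))
  expect_equal(mclust::adjustedRandIndex(
    cl1$labels[common], cl2$labels[common]), 1)
})

test_that("planted two-subtype structure is recovered exactly", {
  d <- cohortDesign(10, 14)
  b <- simulateCohort(d, cohortParams(nGenes = 800, seed = 17,
    subtypeShift = 1.5,   # 3x the protein noise s.d. of 0.5
    missingness = list(cnv = 0, mrna = 0, protein = c(0.05, 0.2),
      phosphosite = c(0.2, 0.6))))
  prot <- b$matrices$protein
  pdxOnly <- OmicsMatrix(
    omicsValues(prot)[, d$sample_id, drop = FALSE], "protein")
  mk <- selectVariableMarkers(pdxOnly, sdThreshold = 0.7)
  expect_gt(length(mk), 20)
  expect_gt(mean(mk %in% b$truth$subtypeMarkers$gene), 0.9)
  cl <- clusterSamples(pdxOnly, markers = mk, k = 2)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(
    cl$labels[d$sample_id], d$subtype), 1)
})

test_that("dendrograms export as readable Newick", {
  set.seed(46)
  v <- matrix(rnorm(60), 10, 6,
    dimnames = list(sprintf("F%02d", 1:10), sprintf("s%02d", 1:6)))
  cl <- clusterSamples(OmicsMatrix(v, "protein"), k = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  exportNewick(cl, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, colnames(v))
})

test_that("disjoint missingness between two samples is an error", {
  v <- matrix(rnorm(12), 3, 4,
    dimnames = list(c("F1", "F2", "F3"), c("a", "b", "c", "d")))
  v[1:2, "a"] <- NA
  v[3, "b"] <- NA
  expect_error(clusterSamples(OmicsMatrix(v, "protein"), k = 2),
    "'a' and 'b'|'b' and 'a'")
})

test_that("co-clustering markers keep non-differential, variable genes", {
  set.seed(56)
  n <- 40
  # gene NEUTRAL: same distribution, merged sd 2.5
  # gene SHIFTED: 5 s.d. cohort difference
  # gene FLAT: sd 1.0
  neutral <- rnorm(n)
  neutral <- neutral / sd(neutral) * 2.5  # merged s.d. exactly 2.5
  pdx <- rbind(NEUTRAL = neutral, SHIFTED = rnorm(n, 0, 1),
    FLAT = rnorm(n, 0, 1))
  hum <- rbind(NEUTRAL = neutral, SHIFTED = rnorm(n, 5, 1),
    FLAT = rnorm(n, 0, 1))
  colnames(pdx) <- sprintf("p%02d", 1:n)
  colnames(hum) <- sprintf("h%02d", 1:n)
  res <- coClusteringMarkers(OmicsMatrix(pdx, "protein"),
    OmicsMatrix(hum, "protein"))
  expect_true("NEUTRAL" %in% res$markers)
  expect_false("SHIFTED" %in% res$markers)  # q ~ 0
  expect_false("FLAT" %in% res$markers)     # fails the s.d. gate
  st <- res$stats
  expect_lt(st$q[st$gene == "SHIFTED"], 0.05)
})

test_that("cohort-batch-filtered markers cluster merged cohorts by subtype", {
  d <- cohortDesign(10, 14, nHuman = 40)
  b <- simulateCohort(d, cohortParams(nGenes = 600, seed = 27,
    subtypeShift = 1.5, cohortShiftProp = 0.6, cohortShiftSd = 1.5,
    missingness = list(cnv = 0, mrna = 0, protein = c(0.05, 0.3),
      phosphosite = c(0.2, 0.6))))
  v <- omicsValues(b$matrices$protein)
  pdx <- OmicsMatrix(v[, d$sample_id[d$cohort == "pdx"]], "protein")
  hum <- OmicsMatrix(v[, d$sample_id[d$cohort == "human"]], "protein")
  cc <- coClusteringMarkers(pdx, hum, sdThreshold = 0.7)
  mk <- intersect(cc$markers, b$truth$subtypeMarkers$gene)
  expect_gt(length(mk), 10)
  merged <- OmicsMatrix(v[, d$sample_id], "protein")
  cl <- clusterSamples(merged, markers = mk, k = 2)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(cl$labels[d$sample_id], d$subtype)
  expect_equal(ari, 1)
  # and the clusters do not simply follow the cohort tag
  ariCohort <- mclust::adjustedRandIndex(
    cl$labels[d$sample_id], d$cohort)
  expect_lt(ariCohort, 0.2)
})
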