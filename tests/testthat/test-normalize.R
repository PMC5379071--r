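# Gene collapsing ------------------------------------------------------

test_that("two-row genes keep the higher-mean row, singletons pass through", {
  m <- toyMatrix(rbind(c(1, 2, 3), c(4, 5, 6), c(9, 9, 9)),
    features = c("GA|t1", "GA|t2", "GB"), level = "mrna")
  out <- omicsValues(collapseToGene(m))
  expect_identical(rownames(out), c("GA", "GB"))
  expect_identical(unname(out["GA", ]), c(4, 5, 6))
  expect_identical(unname(out["GB", ]), c(9, 9, 9))
})

test_that("three-row genes keep the most connected row; ties break by mean", {
  # rows A and B are exactly correlated (B = A + 1), C anti-correlated;
  # connectivity sums computed by brute force on the same toy grid
  a <- c(0, 1, 2, 3, 4, 5)
  m <- toyMatrix(rbind(a, a + 1, rev(a)),
    features = c("G|r1", "G|r2", "G|r3"), level = "protein")
  cc <- cor(t(rbind(a, a + 1, rev(a))))
  conn <- rowSums(cc) - 1
  expect_equal(conn[[1]], conn[[2]])     # exact connectivity tie
  expect_lt(conn[[3]], conn[[1]])        # anti-correlated row loses
  out <- omicsValues(collapseToGene(m))
  expect_identical(unname(out["G", ]), a + 1) # higher-mean of the tied pair
})

test_that("genes without enough pairwise-complete samples fall back to mean", {
  m <- toyMatrix(rbind(
    c(1, 2, NA, NA, NA, NA),
    c(NA, NA, 5, 6, NA, NA),
    c(NA, NA, NA, NA, 2, 1)),
    features = c("G|a", "G|b", "G|c"), level = "protein")
  out <- collapseToGene(m)
  expect_identical(attr(out, "collapse_fallback"), "G")
  expect_identical(unname(omicsValues(out)["G", 3:4]), c(5, 6))
})

test_that("collapsing preserves the distinct gene set", {
  set.seed(42)
  n <- 30
  feats <- sprintf("G%02d|t%d", sample(10, n, TRUE), seq_len(n))
  m <- toyMatrix(matrix(rnorm(n * 8), n, 8), features = feats,
    level = "mrna")
  out <- collapseToGene(m)
  expect_setequal(features(out), unique(sub("\\|.*", "", feats)))
})

# Mixture centering ----------------------------------------------------

test_that("mixture centering recovers the dominant component of a spiked column", {
  set.seed(101)
  x <- matrix(c(rnorm(1800, 0.5, 0.2), rnorm(200, 2.0, 0.5)), ncol = 1,
    dimnames = list(sprintf("F%04d", 1:2000), "s1"))
  mc <- mixtureCenter(OmicsMatrix(x, "protein"))
  expect_lt(abs(mc$fits$offset - 0.5), 0.03)
  expect_identical(mc$fits$basis, "mixture")
  # re-fitting the centered column: dominant mean back at zero
  mc2 <- mixtureCenter(mc$matrix)
  expect_lt(abs(mc2$fits$offset), 0.01)
})

test_that("a plain Gaussian column is centered at its mean, not split", {
  set.seed(7)
  x <- matrix(rnorm(2000), ncol = 1,
    dimnames = list(sprintf("F%04d", 1:2000), "s1"))
  mc <- mixtureCenter(OmicsMatrix(x, "protein"))
  expect_lt(abs(mc$fits$offset), 0.05)
})

test_that("mixture parameters agree with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(33)
  x <- c(rnorm(1500, 0.4, 0.25), rnorm(500, 2.2, 0.4))
  fit <- fitGaussianMixture(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  ours <- sort(fit$mu)
  theirs <- sort(as.numeric(mc$parameters$mean))
  expect_equal(ours, theirs, tolerance = 0.05)
})

test_that("degenerate columns fall back to the median", {
  x <- matrix(c(rep(1.25, 60), rnorm(60)), ncol = 2,
    dimnames = list(sprintf("F%02d", 1:60), c("s1", "s2")))
  mc <- mixtureCenter(OmicsMatrix(x, "protein"))
  expect_identical(mc$fits$basis[1], "median")
  expect_equal(mc$fits$offset[1], 1.25)
  expect_true(all(omicsValues(mc$matrix)[, 1] == 0))
})

test_that("centering is translation-equivariant (idempotent offsets)", {
  set.seed(5)
  x <- matrix(c(rnorm(400, 1, 0.3), rnorm(100, 3, 0.5)), ncol = 1,
    dimnames = list(sprintf("F%03d", 1:500), "s1"))
  m <- OmicsMatrix(x, "phosphosite")
  off1 <- mixtureCenter(m)$fits$offset
  off2 <- mixtureCenter(OmicsMatrix(x - 2.5, "phosphosite"))$fits$offset
  expect_equal(off1 - 2.5, off2, tolerance = 1e-9)
})

test_that("under-observed columns are rejected", {
  x <- matrix(c(rnorm(60), rep(NA, 55), rnorm(5)), ncol = 2,
    dimnames = list(sprintf("F%02d", 1:60), c("s1", "s2")))
  expect_error(mixtureCenter(OmicsMatrix(x, "protein")), "s2")
})

# Observation filter ---------------------------------------------------

test_that("rows below the observation threshold are dropped, order kept", {
  set.seed(1)
  v <- matrix(rnorm(24 * 4), 4, 24,
    dimnames = list(c("A", "B", "C", "D"), sprintf("s%02d", 1:24)))
  v["B", 1:15] <- NA   # 9 observed of 24
  v["D", 1:14] <- NA   # 10 observed
  m <- OmicsMatrix(v, "protein")
  out <- filterMinObserved(m, 10)
  expect_identical(features(out), c("A", "C", "D"))
  expect_identical(attr(out, "dropped"), "B")
  all_na <- v; all_na["C", ] <- NA
  out1 <- filterMinObserved(OmicsMatrix(all_na, "protein"), 1)
  expect_identical(features(out1), c("A", "B", "D"))
})

test_that("raising the observation threshold never adds rows", {
  set.seed(2)
  v <- matrix(rnorm(24 * 50), 50, 24,
    dimnames = list(sprintf("F%02d", 1:50), sprintf("s%02d", 1:24)))
  v[matrix(runif(length(v)) < 0.5, nrow(v))] <- NA
  m <- OmicsMatrix(v, "protein")
  prev <- features(m)
  for (k in c(1, 5, 10, 15, 20)) {
    cur <- features(filterMinObserved(m, k))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("CNV re-referencing zeroes the per-gene cohort mean", {
  set.seed(3)
  v <- matrix(rnorm(40, mean = 2), 4, 10,
    dimnames = list(sprintf("G%d", 1:4), sprintf("s%02d", 1:10)))
  out <- omicsValues(centerCnv(OmicsMatrix(v, "cnv")))
  expect_equal(unname(rowMeans(out)), rep(0, 4), tolerance = 1e-12)
})
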