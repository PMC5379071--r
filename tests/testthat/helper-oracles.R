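# Brute-force oracles kept deliberately independent of the package's
# implementation paths: direct formulas, exhaustive enumeration, and
# hand-rolled interpolation.

# Benjamini-Hochberg step-up, straight from the definition.
bhBrute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# Linear-interpolation quantile (h = (n - 1) p) on the sorted values.
quantileBrute <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Direct high-side IQR fence test: x > Q3 + 1.5 IQR.
fenceBrute <- function(x) {
  q1 <- quantileBrute(x, 0.25)
  q3 <- quantileBrute(x, 0.75)
  x > q3 + 1.5 * (q3 - q1)
}

# Exhaustive two-sample rank-sum test: enumerate every assignment of the
# pooled ranks to the in-group, two-sided p = 2 min(P(W<=w), P(W>=w)).
wilcoxEnumP <- function(inVals, outVals) {
  pooled <- c(inVals, outVals)
  r <- rank(pooled)
  nIn <- length(inVals)
  w <- sum(r[seq_len(nIn)])
  sums <- combn(r, nIn, sum)
  min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
}

# Exhaustive two-sample KS: D as the max ECDF gap, p as the fraction of
# label assignments reaching at least the observed D.
ksD <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(fa - fb))
}
ksEnumP <- function(inVals, outVals) {
  pooled <- c(inVals, outVals)
  nIn <- length(inVals)
  dObs <- ksD(inVals, outVals)
  idx <- combn(length(pooled), nIn)
  ds <- apply(idx, 2, function(i) ksD(pooled[i], pooled[-i]))
  mean(ds >= dObs - 1e-12)
}

# Small fixed-matrix builder.
toyMatrix <- function(values, level = "protein",
                      features = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(features)) features <- sprintf("F%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(features, samples)
  OmicsMatrix(m, level)
}
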