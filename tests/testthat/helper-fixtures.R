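# shared fixtures, all built in code at test time

# a small diurnal experiment with named genes on the 1/2/4/8/12-h grid
tinyExperiment <- function(p = 5, seed = 1, amplitude = 1, noiseSd = 0.25,
                           nReplicates = 1) {
  truth <- makeSparseGGM(p, 0.2, 0.3, seed = seed)
  simulateDiurnalMatrix(truth, amplitude = amplitude, noiseSd = noiseSd,
                        nReplicates = nReplicates, seed = seed)
}

# random positive-definite correlation matrix of dimension d
randomCorr <- function(d, n = 50) {
  cor(matrix(rnorm(n * d), n, d))
}

# adjusted Rand index between two partitions
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumIj <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  expect <- sumI * sumJ / choose(sum(tab), 2)
  maxIdx <- (sumI + sumJ) / 2
  (sumIj - expect) / (maxIdx - expect)
}

# independent Mann-Whitney enumeration oracle: U counted directly from
# pairwise comparisons (not rank sums), two-sided by |U - mu| exceedance
enumMWOracle <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled)
  nx <- length(x)
  uOf <- function(xi, yi) sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  mu <- nx * (N - nx) / 2
  uObs <- uOf(x, y)
  combs <- combn(N, nx)
  uAll <- apply(combs, 2, function(idx) uOf(pooled[idx], pooled[-idx]))
  list(U = uObs, p = mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9))
}

# polygon helpers for the circularity suite (shoelace area, edge lengths)
polygonArea <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
polygonPerimeter <- function(xy) {
  d <- rbind(diff(xy), xy[1, ] - xy[nrow(xy), ])
  sum(sqrt(rowSums(d^2)))
}
ellipsePolygon <- function(a, b, k = 20000) {
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  cbind(a * cos(th), b * sin(th))
}
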