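# Profile clustering and light/dark response-group assignment.  Significant
# diurnal profiles are standardised per gene, clustered with k-means
# (k-means++ seeding, several restarts, best within-cluster sum of squares)
# and each cluster centroid is mapped to one of four response groups:
#   A  dark-induced / light-repressed
#   B  light-induced / dark-repressed
#   C  near-flat with a positive step at the dark-to-light transition
#   D  near-flat with a negative step at the dark-to-light transition

#' Standardise expression profiles
#'
#' Centres and scales every gene profile to mean 0 and standard deviation 1.
#' Zero-variance profiles become zero vectors and are flagged in the
#' `"constant"` attribute.
#'
#' @param x a [DiurnalExperiment-class] or genes x arrays matrix.
#' @return matrix of standardised profiles with a logical `"constant"`
#'   attribute.
#' @export
standardizeProfiles <- function(x) {
  Y <- if (is(x, "DiurnalExperiment")) SummarizedExperiment::assay(x, "exprs")
       else as.matrix(x)
  mu <- rowMeans(Y)
  s <- apply(Y, 1L, sd)
  constant <- s <= .Machine$double.eps * sqrt(ncol(Y))
  s[constant] <- 1
  out <- (Y - mu) / s
  out[constant, ] <- 0
  if (any(constant)) {
    warning(sprintf("%d constant profile(s) set to zero vectors",
                    sum(constant)))
  }
  attr(out, "constant") <- unname(constant)
  out
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest chosen centre
kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[centers[1L], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = prob)
    dn <- rowSums((X - matrix(X[centers[j + 1L], ], n, ncol(X),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  X[centers, , drop = FALSE]
}

#' Cluster expression profiles with k-means
#'
#' Lloyd's algorithm from k-means++ seedings; the best of `nRestarts` runs
#' by total within-cluster sum of squares is returned.  Deterministic for a
#' fixed `seed`.
#'
#' @param X matrix of (standardised) profiles, genes in rows.
#' @param k number of clusters (default 30).
#' @param seed optional RNG seed.
#' @param nRestarts independent k-means++ starts (default 10).
#' @param iterMax Lloyd iterations per start.
#' @return list with `cluster` (named integer vector), `centers`
#'   (k x arrays matrix), `wcss` (total within-cluster sum of squares).
#' @export
clusterProfiles <- function(X, k = 30L, seed = NULL, nRestarts = 10L,
                            iterMax = 100L) {
  X <- as.matrix(X)
  k <- as.integer(k)
  stopIfNot(k >= 1L, "'k' must be at least 1")
  if (k > nrow(X)) stop("k exceeds the number of genes")
  withSeed(seed, {
    best <- NULL
    for (r in seq_len(nRestarts)) {
      init <- kmeansppCenters(X, k)
      # duplicate seeds can collapse; jitter identical rows minimally
      if (anyDuplicated(init)) {
        init <- init + rnorm(length(init), sd = 1e-8)
      }
      km <- suppressWarnings(
        stats::kmeans(X, centers = init, iter.max = iterMax,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    list(cluster = setNames(best$cluster, rownames(X)),
         centers = best$centers, wcss = best$tot.withinss)
  })
}

# index of the dark -> light transition: position i such that array i is the
# last dark array and i+1 (cyclically) the first light array
transitionIndex <- function(phase) {
  phase <- checkPhase(phase)
  n <- length(phase)
  if (all(phase == "dark") || all(phase == "light")) {
    stop("phase vector must contain both dark and light arrays")
  }
  i <- which(phase[-n] == "dark" & phase[-1L] == "light")
  if (length(i)) return(i[1L])
  if (phase[n] == "dark" && phase[1L] == "light") return(n)
  stop("no dark-to-light transition found in phase vector")
}

#' Assign a profile centroid to a light/dark response group
#'
#' Let `c` be the Pearson correlation of the centroid with the light
#' indicator (light = 1, dark = 0) and `d` the centroid step across the
#' dark-to-light transition in centroid standard-deviation units.  The rule
#' is: `A` if `c <= -tau`; `B` if `c >= tau`; otherwise `C` if `d > delta`,
#' else `D`.  The label is invariant to adding a constant to the centroid
#' and to positive rescaling.
#'
#' @param centroid numeric centroid (or single-profile) vector.
#' @param phase per-array phase labels aligned with `centroid`.
#' @param tau correlation threshold for the tightly regulated groups
#'   (default 0.5).
#' @param delta transition-step threshold in sd units (default 0.5).
#' @return one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @examples
#' ph <- rep(c("dark", "light"), each = 5)
#' assignGroup(as.numeric(ph == "light"), ph)  # "B"
#' assignGroup(as.numeric(ph == "dark"), ph)   # "A"
#' @export
assignGroup <- function(centroid, phase, tau = 0.5, delta = 0.5) {
  centroid <- as.numeric(centroid)
  phase <- checkPhase(phase, length(centroid))
  ti <- transitionIndex(phase)
  light <- as.numeric(phase == "light")
  s <- sd(centroid)
  cc <- if (s > 0) cor(centroid, light) else 0
  if (cc <= -tau) return("A")
  if (cc >= tau) return("B")
  nxt <- if (ti == length(centroid)) 1L else ti + 1L
  d <- if (s > 0) (centroid[nxt] - centroid[ti]) / s else 0
  if (d > delta) "C" else "D"
}

#' Cluster genes and assign response groups
#'
#' Standardises profiles, clusters them with [clusterProfiles()] and labels
#' every cluster centroid with [assignGroup()].
#'
#' @param x a [DiurnalExperiment-class].
#' @param k number of clusters (default 30).
#' @param seed optional RNG seed.
#' @param tau,delta group-assignment thresholds, see [assignGroup()].
#' @param ... passed to [clusterProfiles()].
#' @return list with `assignment` (data.frame `gene_id`, `cluster`,
#'   `group`), `centers`, `clusterGroups` (group label per cluster), `wcss`.
#' @export
clusterGenes <- function(x, k = 30L, seed = NULL, tau = 0.5, delta = 0.5,
                         ...) {
  stopifnot(is(x, "DiurnalExperiment"))
  Xstd <- suppressWarnings(standardizeProfiles(x))
  cl <- clusterProfiles(Xstd, k = k, seed = seed, ...)
  ph <- arrayPhase(x)
  grp <- vapply(seq_len(nrow(cl$centers)), function(i) {
    assignGroup(cl$centers[i, ], ph, tau = tau, delta = delta)
  }, character(1L))
  list(assignment = data.frame(gene_id = names(cl$cluster),
                               cluster = unname(cl$cluster),
                               group = grp[cl$cluster],
                               row.names = NULL, stringsAsFactors = FALSE),
       centers = cl$centers, clusterGroups = grp, wcss = cl$wcss)
}
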