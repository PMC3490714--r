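# Time-course significance testing: each gene's profile is tested against a
# flat line by comparing the residual sum of squares of an intercept-only
# null model with a natural cubic spline alternative, summarised as an
# F-statistic.  P-values come from permutation of array labels (the small-n
# default) or the parametric F distribution, and are converted to q-values
# with a Storey-style FDR transform.

#' Build a natural cubic spline basis for a time course
#'
#' The design has an intercept column followed by `df` natural cubic spline
#' columns (zero second derivatives at the boundary knots, internal knots at
#' quantiles of the sampling times).  Spline columns are centred so the
#' intercept alone spans the null (flat-line) model.
#'
#' @param timeH per-array sampling times in hours.
#' @param df spline basis dimension (default 3).
#' @return a [SplineBasis-class].
#' @examples
#' b <- splineBasis(rep(c(1, 2, 4, 8, 12), 2), df = 3)
#' dim(b@design)  # 10 x 4
#' @export
splineBasis <- function(timeH, df = 3) {
  timeH <- as.numeric(timeH)
  df <- as.integer(df)
  stopIfNot(df >= 1L, "'df' must be at least 1")
  ut <- unique(timeH)
  if (length(ut) < 2L) stop("no temporal variation: constant time vector")
  if (length(ut) < df + 2L) {
    stop(sprintf("df = %d too large for %d distinct timepoints (need >= df + 2)",
                 df, length(ut)))
  }
  sp <- splines::ns(timeH, df = df)
  sp <- scale(sp, center = TRUE, scale = FALSE)
  design <- cbind(1, sp)
  dimnames(design) <- list(NULL, c("intercept", paste0("ns", seq_len(df))))
  if (qr(design)$rank < ncol(design)) {
    stop("spline design is rank deficient for these timepoints")
  }
  new("SplineBasis", timepoints = timeH, df = df, design = design)
}

# residual sums of squares for all rows of Y under the spline design
rssBoth <- function(Y, basis) {
  Q <- qr.Q(qr(basis@design))
  fitted2 <- rowSums((Y %*% Q)^2)
  tot2 <- rowSums(Y^2)
  rssAlt <- pmax(tot2 - fitted2, 0)
  rssNull <- rowSums((Y - rowMeans(Y))^2)
  # the null model is nested in the alternative
  rssAlt <- pmin(rssAlt, rssNull)
  list(null = rssNull, alt = rssAlt)
}

#' Flat-line versus spline fit for one expression profile
#'
#' @param y numeric expression profile, one value per array.
#' @param basis a [SplineBasis-class] whose design has `length(y)` rows.
#' @return named numeric vector `c(rss_null = , rss_alt = )`: residual sums
#'   of squares about the mean and from the spline least-squares fit.
#' @export
fitFlatVsSpline <- function(y, basis) {
  stopifnot(is(basis, "SplineBasis"))
  y <- as.numeric(y)
  if (length(y) != nrow(basis@design)) {
    stop("profile length must match the basis design")
  }
  if (!all(is.finite(y))) stop("non-finite expression values")
  r <- rssBoth(matrix(y, nrow = 1L), basis)
  c(rss_null = r$null, rss_alt = r$alt)
}

#' F-statistic for the flat-vs-spline model comparison
#'
#' `f = ((rssNull - rssAlt) / df) / (rssAlt / (n - df - 1))`.  When the two
#' models fit equally well `f = 0`; a perfect spline fit with residual null
#' misfit yields `Inf` (handled by the permutation scheme as a p-value at
#' the permutation floor).
#'
#' @param rssNull,rssAlt residual sums of squares of the nested models.
#' @param n number of arrays.
#' @param df spline basis dimension.
#' @return numeric F-statistic(s), `>= 0`.
#' @export
fStatistic <- function(rssNull, rssAlt, n, df) {
  if (n <= df + 1) stop("need n > df + 1 arrays")
  num <- pmax(rssNull - rssAlt, 0) / df
  den <- rssAlt / (n - df - 1)
  f <- ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den))
  as.numeric(f)
}

#' Permutation p-values for the time-course F-test
#'
#' Array labels are permuted identically across genes; for each gene
#' `p = (1 + #\{permuted f >= observed f\}) / (1 + nPerm)`.  Zero-variance
#' genes have `f = 0` and `p = 1`.
#'
#' @param fStats observed per-gene F-statistics.
#' @param Y genes x arrays expression matrix the statistics came from.
#' @param basis the [SplineBasis-class] used.
#' @param nPerm number of permutations (default 1000).
#' @param seed optional RNG seed for the permutation stream.
#' @return numeric vector of p-values in (0, 1].
#' @export
dePvalues <- function(fStats, Y, basis, nPerm = 1000L, seed = NULL) {
  stopifnot(is(basis, "SplineBasis"))
  Y <- as.matrix(Y)
  nPerm <- as.integer(nPerm)
  stopIfNot(nPerm >= 1L, "'nPerm' must be at least 1")
  n <- ncol(Y)
  df <- basis@df
  withSeed(seed, {
    exceed <- integer(nrow(Y))
    for (b in seq_len(nPerm)) {
      perm <- sample.int(n)
      r <- rssBoth(Y[, perm, drop = FALSE], basis)
      fb <- fStatistic(r$null, r$alt, n, df)
      exceed <- exceed + (fb >= fStats)
    }
    (1 + exceed) / (1 + nPerm)
  })
}

#' Storey-style q-values
#'
#' Estimates the null proportion `pi0` with the `lambda = 0.5` plug-in
#' (`pi0 = #\{p > lambda\} / ((1 - lambda) m)`, clamped to `[1/m, 1]`) and
#' applies the monotone step-up transform `q_(i) = min_{j >= i}
#' pi0 * m * p_(j) / j`.  With `pi0 = 1` this reduces to Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param lambda tuning point of the pi0 plug-in estimator.
#' @param pi0 optionally fix the null proportion instead of estimating it.
#' @return vector of q-values, same order as `p`.
#' @export
qvalueStorey <- function(p, lambda = 0.5, pi0 = NULL) {
  p <- as.numeric(p)
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- sum(p > lambda) / ((1 - lambda) * m)
    pi0 <- min(1, max(pi0, 1 / m))
  }
  ord <- order(p)
  q <- pi0 * m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Time-course differential expression test
#'
#' Runs the flat-vs-spline comparison for every gene of a diurnal
#' experiment: natural cubic spline fit, F-statistics, permutation (or
#' parametric) p-values and Storey q-values.
#'
#' The spline is fitted over the absolute hour of the diurnal cycle
#' (dark hours first, then light; see [cycleHour()]), so dark and light
#' arrays sampled the same number of hours after their respective
#' transitions occupy distinct positions on the 24-h course.
#'
#' @param x a [DiurnalExperiment-class] or a genes x arrays matrix.
#' @param timeH sampling times; taken from `x` when it is a
#'   `DiurnalExperiment`.  For a plain matrix this is the time coordinate
#'   used directly unless `phase` is also given.
#' @param phase optional per-array `"dark"`/`"light"` labels for a plain
#'   matrix; when present, `timeH` is interpreted as hours since the last
#'   transition and mapped through [cycleHour()].
#' @param darkHours,period cycle geometry for [cycleHour()] (defaults 12
#'   and 24).
#' @param df spline basis dimension (default 3).
#' @param nPerm permutations for the p-value (default 1000).
#' @param qThreshold significance cutoff on the q-value (default 0.01).
#' @param method `"permutation"` (default; recommended at diurnal-course
#'   sample sizes) or `"parametric"` (F distribution with `df` and
#'   `n - df - 1` degrees of freedom).
#' @param seed optional RNG seed for the permutation stream.
#' @return data.frame with columns `gene_id`, `rss_null`, `rss_alt`,
#'   `f_stat`, `p_value`, `q_value`, `significant`.
#' @examples
#' truth <- makeSparseGGM(12, 0.1, 0.3, seed = 7)
#' de <- simulateDiurnalMatrix(truth, amplitude = 2, seed = 7)
#' res <- deTest(de, nPerm = 200, seed = 7)
#' head(res)
#' @export
deTest <- function(x, timeH = NULL, phase = NULL, df = 3, nPerm = 1000L,
                   qThreshold = 0.01,
                   method = c("permutation", "parametric"), seed = NULL,
                   darkHours = 12, period = 24) {
  method <- match.arg(method)
  if (is(x, "DiurnalExperiment")) {
    Y <- SummarizedExperiment::assay(x, "exprs")
    timeH <- cycleHour(arrayTime(x), arrayPhase(x), darkHours, period)
  } else {
    Y <- as.matrix(x)
    if (is.null(timeH)) stop("'timeH' is required for a plain matrix")
    if (!is.null(phase)) {
      timeH <- cycleHour(timeH, checkPhase(phase, ncol(Y)), darkHours,
                         period)
    }
  }
  stopIfNot(qThreshold > 0 && qThreshold < 1, "'qThreshold' must be in (0,1)")
  basis <- splineBasis(timeH, df = df)
  n <- ncol(Y)
  r <- rssBoth(Y, basis)
  f <- fStatistic(r$null, r$alt, n, basis@df)
  constant <- r$null <= .Machine$double.eps * n
  f[constant] <- 0
  p <- if (method == "permutation") {
    dePvalues(f, Y, basis, nPerm = nPerm, seed = seed)
  } else {
    pf(f, basis@df, n - basis@df - 1, lower.tail = FALSE)
  }
  p[constant] <- 1
  q <- qvalueStorey(p)
  data.frame(gene_id = rownames(Y), rss_null = r$null, rss_alt = r$alt,
             f_stat = f, p_value = p, q_value = q,
             significant = q <= qThreshold, row.names = NULL,
             stringsAsFactors = FALSE)
}
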