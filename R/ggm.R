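# Small-sample graphical Gaussian model inference.  With far more genes than
# arrays the sample covariance is singular, so the correlation matrix is
# shrunk toward the identity with the analytic (Ledoit-Wolf / Schafer-
# Strimmer) intensity before inversion.  Partial correlations are read off
# the standardised inverse, their significance calibrated by fitting the
# two-component mixture
#   f(r) = eta0 * f0(r; kappa) + (1 - eta0) * fA(r)
# to the observed off-diagonal values, and edges selected by FDR q-value.

#' Pearson correlation matrix of a gene expression matrix
#'
#' @param x a [DiurnalExperiment-class] or genes x arrays matrix (genes are
#'   the variables, arrays the observations).
#' @param dropConstant drop zero-variance genes with a warning instead of
#'   failing.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(x, dropConstant = FALSE) {
  Y <- if (is(x, "DiurnalExperiment")) SummarizedExperiment::assay(x, "exprs")
       else as.matrix(x)
  if (ncol(Y) < 3L) stop("at least 3 arrays are required")
  v <- apply(Y, 1L, var)
  if (any(v == 0)) {
    if (!dropConstant) {
      stop("zero-variance gene(s) present; set dropConstant = TRUE to drop")
    }
    warning(sprintf("dropping %d zero-variance gene(s)", sum(v == 0)))
    Y <- Y[v > 0, , drop = FALSE]
  }
  r <- cor(t(Y))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  pmin(pmax(r, -1), 1)
}

#' Partial correlation of two variables given a third
#'
#' `pr_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`.
#'
#' @param rxy,rxz,ryz pairwise Pearson correlations in \[-1, 1\].
#' @return the partial correlation of x and y given z.
#' @examples
#' partialCorr3(0.6, 0.5, 0.5)  # 0.35 / 0.75
#' @export
partialCorr3 <- function(rxy, rxz, ryz) {
  if (any(abs(c(rxy, rxz, ryz)) > 1)) stop("correlations must lie in [-1, 1]")
  if (any(abs(c(rxz, ryz)) >= 1)) {
    stop("degenerate conditioning: |r_xz| or |r_yz| equals 1")
  }
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Full-order partial correlations from a correlation matrix
#'
#' Inverts the (shrunk) correlation matrix `R` to `S = R^-1` and returns
#' `pcor_xy = -s_xy / sqrt(s_xx * s_yy)` with a zero diagonal.
#'
#' @param r invertible symmetric correlation (or covariance) matrix.
#' @return symmetric partial-correlation matrix, zero diagonal.
#' @export
partialCorFromCorrelation <- function(r) {
  r <- as.matrix(r)
  S <- tryCatch(chol2inv(chol(r)), error = function(e) {
    stop("correlation matrix is not positive definite; shrink it first")
  })
  d <- sqrt(diag(S))
  pc <- -S / outer(d, d)
  diag(pc) <- 0
  pc <- (pc + t(pc)) / 2
  dimnames(pc) <- dimnames(r)
  pc
}

#' Shrinkage estimate of the correlation matrix
#'
#' Shrinks the sample correlation toward the identity,
#' `r* = (1 - lambda) r + lambda I`, with the analytic intensity
#' `lambda = sum_(i<j) Var-hat(r_ij) / sum_(i<j) r_ij^2` (clamped to
#' \[0, 1\]) that minimises the estimated mean squared error.  The result is
#' positive definite even when genes far outnumber arrays.
#'
#' @inheritParams correlationMatrix
#' @return list with `r` (shrunk correlation matrix) and `lambda`.
#' @export
shrinkCorrelation <- function(x, dropConstant = FALSE) {
  Y <- if (is(x, "DiurnalExperiment")) SummarizedExperiment::assay(x, "exprs")
       else as.matrix(x)
  r <- correlationMatrix(Y, dropConstant = dropConstant)
  keep <- rownames(r)
  if (!is.null(keep) && nrow(r) < nrow(Y)) Y <- Y[keep, , drop = FALSE]
  n <- ncol(Y)
  xs <- t(scale(t(Y)))            # unit-variance rows (sd with n-1)
  # Var-hat(r_ij) = n / (n-1)^3 * sum_k (w_kij - mean_k w_kij)^2,
  # with w_kij = xs_ik * xs_jk; computed via cross products
  sumW2 <- tcrossprod(xs^2)
  sumW <- tcrossprod(xs)          # equals (n-1) * r
  varR <- n / (n - 1)^3 * (sumW2 - sumW^2 / n)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom > 0) sum(varR[off]) / denom else 1
  lambda <- min(1, max(0, lambda))
  rStar <- (1 - lambda) * r
  diag(rStar) <- 1
  list(r = rStar, lambda = lambda)
}

#' Null density of an observed partial correlation
#'
#' `f0(r; kappa) = (1 - r^2)^((kappa - 3) / 2) * Gamma(kappa / 2) /
#' (sqrt(pi) * Gamma((kappa - 1) / 2))` on \[-1, 1\].  At `kappa = 3` this
#' is the uniform density 1/2.
#'
#' @param r partial correlation value(s).
#' @param kappa degrees of freedom (> 2).
#' @return density value(s).
#' @export
nullPcorDensity <- function(r, kappa) {
  stopIfNot(kappa > 2, "'kappa' must exceed 2")
  out <- rep(0, length(r))
  ok <- abs(r) < 1
  out[ok] <- exp(((kappa - 3) / 2) * log1p(-r[ok]^2) +
                 lgamma(kappa / 2) - 0.5 * log(pi) - lgamma((kappa - 1) / 2))
  if (kappa == 3) out[abs(r) == 1] <- 0.5
  out
}

# two-sided null p-value: under f0, r^2 ~ Beta(1/2, (kappa-1)/2)
nullPcorPvalue <- function(r, kappa) {
  pbeta(r^2, 0.5, (kappa - 1) / 2, lower.tail = FALSE)
}

# draw m values from f0 with the given kappa
rNullPcor <- function(m, kappa) {
  sqrt(rbeta(m, 0.5, (kappa - 1) / 2)) * sign(runif(m) - 0.5)
}

#' Fit the null/alternative mixture to observed partial correlations
#'
#' Maximum likelihood over a log-spaced grid of `kappa` values, with the
#' null proportion `eta0` profile-maximised at each grid point.  The
#' alternative component `fA` is the maximally diffuse uniform density on
#' \[-1, 1\] (the `kappa = 3` form), which keeps `eta0` identifiable.
#' Likelihood ties are broken toward larger `kappa` (more conservative
#' p-values).  The default grid reaches very large `kappa` because strong
#' shrinkage can compress the null partial correlations to a tiny spread,
#' whose effective degrees of freedom far exceed the sample size.
#'
#' @param pc vector of observed off-diagonal partial correlations in
#'   (-1, 1); at least 10 values.
#' @param kappaGrid grid of candidate degrees of freedom (default 300
#'   log-spaced points from 3 to 1e7).
#' @return a [MixtureFit-class].
#' @export
fitNullMixture <- function(pc, kappaGrid = NULL) {
  pc <- as.numeric(pc)
  if (length(pc) < 10L) stop("need at least 10 partial correlations")
  if (any(!is.finite(pc)) || any(abs(pc) >= 1)) {
    stop("partial correlations must lie strictly inside (-1, 1)")
  }
  if (is.null(kappaGrid)) {
    kappaGrid <- exp(seq(log(3), log(1e7), length.out = 300L))
  }
  fA <- 0.5
  lls <- numeric(length(kappaGrid))
  etas <- numeric(length(kappaGrid))
  for (i in seq_along(kappaGrid)) {
    f0v <- nullPcorDensity(pc, kappaGrid[i])
    ll <- function(eta) sum(log(eta * f0v + (1 - eta) * fA))
    opt <- optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(opt$maximum, 0, 1)
    vals <- c(opt$objective, ll(0), ll(1))
    j <- which.max(vals)
    etas[i] <- cand[j]
    lls[i] <- vals[j]
  }
  best <- max(lls)
  pick <- max(which(lls >= best - 1e-8))   # ties -> larger kappa
  new("MixtureFit", eta0 = etas[pick], kappa = kappaGrid[pick],
      logLik = lls[pick], n = length(pc))
}

#' Calibrated edge significance for a partial-correlation matrix
#'
#' Two-sided p-values under the fitted null component,
#' `p_xy = 2 (1 - F0(|pcor_xy|; kappa))`, FDR q-values via the same Storey
#' transform used for time-course testing, and the selected edge set
#' `q <= qThreshold` with the sign of the partial correlation.  Diagonal
#' and self-pairs are never tested.
#'
#' @param pcorMat symmetric partial-correlation matrix.
#' @param fit a [MixtureFit-class]; fitted from `pcorMat` when missing.
#' @param qThreshold edge q-value cutoff (default 0.05).
#' @param lambda shrinkage intensity to record in the result.
#' @return a [GGMNetwork-class].
#' @export
edgeSignificance <- function(pcorMat, fit = NULL, qThreshold = 0.05,
                             lambda = NA_real_) {
  pcorMat <- as.matrix(pcorMat)
  ids <- rownames(pcorMat)
  if (is.null(ids)) {
    ids <- sprintf("G%03d", seq_len(nrow(pcorMat)))
    dimnames(pcorMat) <- list(ids, ids)
  }
  stopIfNot(qThreshold > 0 && qThreshold < 1, "'qThreshold' must be in (0,1)")
  ut <- upper.tri(pcorMat)
  pc <- pcorMat[ut]
  if (is.null(fit)) fit <- fitNullMixture(pc)
  stopifnot(is(fit, "MixtureFit"))
  p <- nullPcorPvalue(pc, fit@kappa)
  q <- qvalueStorey(p)
  pm <- qm <- matrix(NA_real_, nrow(pcorMat), ncol(pcorMat),
                     dimnames = dimnames(pcorMat))
  pm[ut] <- p
  qm[ut] <- q
  pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
  qm[lower.tri(qm)] <- t(qm)[lower.tri(qm)]
  idx <- which(ut & qm <= qThreshold, arr.ind = TRUE)
  ed <- data.frame(gene_a = ids[idx[, 1L]], gene_b = ids[idx[, 2L]],
                   pcor = pcorMat[idx], p_value = pm[idx], q_value = qm[idx],
                   sign = ifelse(pcorMat[idx] >= 0, 1L, -1L),
                   stringsAsFactors = FALSE)
  ed <- normalizeEdges(ed)
  rownames(ed) <- NULL
  new("GGMNetwork", pcor = pcorMat, pValues = pm, qValues = qm, edges = ed,
      mixture = fit, lambda = lambda, qThreshold = qThreshold)
}

#' Infer a graphical Gaussian model network from expression data
#'
#' The full small-sample pipeline: shrinkage correlation estimate, matrix
#' inversion to partial correlations, mixture-model calibration and
#' FDR edge selection.
#'
#' @inheritParams correlationMatrix
#' @param qThreshold edge q-value cutoff (default 0.05).
#' @param kappaGrid passed to [fitNullMixture()].
#' @return a [GGMNetwork-class].
#' @examples
#' truth <- makeSparseGGM(15, 0.15, 0.35, seed = 3)
#' de <- simulateDiurnalMatrix(truth, nReplicates = 4, seed = 3)
#' net <- ggmNetwork(de)
#' net
#' @export
ggmNetwork <- function(x, qThreshold = 0.05, dropConstant = FALSE,
                       kappaGrid = NULL) {
  sh <- shrinkCorrelation(x, dropConstant = dropConstant)
  pc <- partialCorFromCorrelation(sh$r)
  fit <- fitNullMixture(pc[upper.tri(pc)], kappaGrid = kappaGrid)
  edgeSignificance(pc, fit = fit, qThreshold = qThreshold,
                   lambda = sh$lambda)
}
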