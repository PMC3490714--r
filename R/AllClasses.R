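#' Diurnal expression experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying a genes x arrays
#' log2 expression matrix in assay `"exprs"`, with per-array diurnal metadata
#' in `colData`: `time_h` (hours since the last light-on / light-off event)
#' and `phase` (`"dark"` or `"light"`).
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [DiurnalExperiment()] for the constructor, [arrayTime()],
#'   [arrayPhase()].
#' @exportClass DiurnalExperiment
setClass("DiurnalExperiment", contains = "SummarizedExperiment")

setValidity("DiurnalExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'exprs' is required")
  } else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(m)) msg <- c(msg, "assay 'exprs' must be numeric")
    if (is.numeric(m) && !all(is.finite(m))) {
      msg <- c(msg, "assay 'exprs' must be finite (no NA/NaN/Inf)")
    }
  }
  if (ncol(object) < 2L) msg <- c(msg, "at least 2 arrays are required")
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn))) {
    msg <- c(msg, "gene ids (rownames) must be present, non-empty and unique")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("time_h", "phase") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'time_h' and 'phase'")
  } else {
    if (!is.numeric(cd$time_h) || anyNA(cd$time_h)) {
      msg <- c(msg, "'time_h' must be numeric without NA")
    }
    ph <- as.character(cd$phase)
    if (anyNA(ph) || !all(ph %in% c("dark", "light"))) {
      msg <- c(msg, "'phase' must be 'dark' or 'light'")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DiurnalExperiment
#'
#' @param values numeric matrix, genes x arrays, on the log2 scale.  Row
#'   names are gene identifiers (unique, non-empty); column names are array
#'   identifiers.
#' @param timeH numeric vector of sampling times, hours since the most recent
#'   light-on (for light arrays) or light-off (for dark arrays) event.
#' @param phase character vector, `"dark"` or `"light"` per array.
#' @param geneIds optional gene identifiers overriding `rownames(values)`.
#'
#' @return A [DiurnalExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(20), 2, 10,
#'             dimnames = list(c("g1", "g2"), paste0("a", 1:10)))
#' de <- DiurnalExperiment(m, timeH = rep(c(1, 2, 4, 8, 12), 2),
#'                         phase = rep(c("dark", "light"), each = 5))
#' arrayPhase(de)
#' @export
DiurnalExperiment <- function(values, timeH, phase, geneIds = rownames(values)) {
  values <- as.matrix(values)
  if (!is.null(geneIds)) rownames(values) <- geneIds
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("array%02d", seq_len(ncol(values)))
  }
  phase <- checkPhase(phase, ncol(values))
  cd <- S4Vectors::DataFrame(time_h = as.numeric(timeH), phase = phase,
                             row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd)
  new("DiurnalExperiment", se)
}

#' Natural cubic spline basis for a diurnal time course
#'
#' @slot timepoints numeric, the per-array sampling times (hours).
#' @slot df integer, dimension of the spline part of the basis.
#' @slot design numeric matrix, arrays x (df + 1): a constant intercept
#'   column followed by `df` centred natural cubic spline columns with zero
#'   second derivatives at the boundary knots.
#' @exportClass SplineBasis
setClass("SplineBasis",
         representation(timepoints = "numeric", df = "integer",
                        design = "matrix"))

setValidity("SplineBasis", function(object) {
  msg <- character()
  d <- object@design
  if (nrow(d) != length(object@timepoints)) {
    msg <- c(msg, "design rows must match timepoints")
  }
  if (ncol(d) != object@df + 1L) msg <- c(msg, "design must have df+1 columns")
  if (ncol(d) >= 1L && any(d[, 1L] != 1)) {
    msg <- c(msg, "first design column must be the intercept")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted null/alternative mixture over observed partial correlations
#'
#' The observed partial correlations r are modelled as
#' `f(r) = eta0 * f0(r; kappa) + (1 - eta0) * fA(r)`, with
#' `f0(r; kappa) = (1 - r^2)^((kappa-3)/2) * Gamma(kappa/2) /
#' (sqrt(pi) * Gamma((kappa-1)/2))` the null density of a partial
#' correlation with `kappa` degrees of freedom, and `fA` a maximally diffuse
#' alternative (the uniform density on \[-1, 1\], i.e. `f0` with kappa = 3).
#'
#' @slot eta0 estimated proportion of null edges, in \[0, 1\].
#' @slot kappa estimated degrees of freedom of the null density (> 2).
#' @slot logLik maximised log-likelihood.
#' @slot n number of partial correlations used in the fit.
#' @seealso [fitNullMixture()], [edgeSignificance()].
#' @exportClass MixtureFit
setClass("MixtureFit",
         representation(eta0 = "numeric", kappa = "numeric",
                        logLik = "numeric", n = "integer"))

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (object@eta0 < 0 || object@eta0 > 1) msg <- c(msg, "eta0 must be in [0,1]")
  if (object@kappa <= 2) msg <- c(msg, "kappa must exceed 2")
  if (length(msg)) msg else TRUE
})

#' Partial-correlation network with calibrated edge significance
#'
#' @slot pcor symmetric matrix of shrinkage partial correlations, zero
#'   diagonal by convention.
#' @slot pValues symmetric matrix of two-sided edge p-values (diagonal NA).
#' @slot qValues symmetric matrix of FDR q-values (diagonal NA).
#' @slot edges data.frame of selected edges (`gene_a`, `gene_b`, `pcor`,
#'   `p_value`, `q_value`, `sign`), endpoints lexicographically ordered so
#'   every undirected edge has one canonical row.
#' @slot mixture the [MixtureFit-class] used to calibrate significance.
#' @slot lambda shrinkage intensity applied to the sample correlation matrix.
#' @slot qThreshold q-value cutoff defining the selected edge set.
#' @seealso [ggmNetwork()], [edgeSignificance()], [edges()], [pcor()].
#' @exportClass GGMNetwork
setClass("GGMNetwork",
         representation(pcor = "matrix", pValues = "matrix",
                        qValues = "matrix", edges = "data.frame",
                        mixture = "MixtureFit", lambda = "numeric",
                        qThreshold = "numeric"))

setValidity("GGMNetwork", function(object) {
  msg <- character()
  pc <- object@pcor
  if (nrow(pc) != ncol(pc)) msg <- c(msg, "pcor must be square")
  if (max(abs(pc - t(pc))) > 1e-8) msg <- c(msg, "pcor must be symmetric")
  if (any(abs(pc) > 1 + 1e-8)) msg <- c(msg, "|pcor| must not exceed 1")
  if (any(diag(pc) != 0)) msg <- c(msg, "pcor diagonal must be zero")
  ut <- upper.tri(object@pValues)
  pv <- object@pValues[ut]
  qv <- object@qValues[ut]
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) msg <- c(msg, "p-values outside [0,1]")
  if (any(qv < 0 | qv > 1, na.rm = TRUE)) msg <- c(msg, "q-values outside [0,1]")
  if (object@qThreshold <= 0 || object@qThreshold >= 1) {
    msg <- c(msg, "qThreshold must be in (0,1)")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth for a planted sparse graphical Gaussian model
#'
#' @slot precision symmetric positive-definite precision matrix with unit
#'   diagonal; its nonzero off-diagonal support is exactly the true edge set.
#' @slot truePcor implied partial-correlation matrix
#'   (`-omega_ij / sqrt(omega_ii * omega_jj)`).
#' @slot trueEdges data.frame (`gene_a`, `gene_b`, `pcor`), canonical order.
#' @slot groups character vector per gene: diurnal response-group shape
#'   `"A"`, `"B"`, `"C"`, `"D"` or `"flat"`.
#' @slot planted data.frame of planted regulator -> target pairs
#'   (`regulator_gene`, `target_gene`), possibly empty.
#' @slot seed integer seed the object was generated from (NA if none).
#' @seealso [makeSparseGGM()], [simulateDiurnalMatrix()].
#' @exportClass GGMGroundTruth
setClass("GGMGroundTruth",
         representation(precision = "matrix", truePcor = "matrix",
                        trueEdges = "data.frame", groups = "character",
                        planted = "data.frame", seed = "integer"))

setValidity("GGMGroundTruth", function(object) {
  msg <- character()
  om <- object@precision
  if (max(abs(om - t(om))) > 1e-10) msg <- c(msg, "precision must be symmetric")
  ev <- min(eigen(om, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) msg <- c(msg, "precision must be positive definite")
  if (length(object@groups) != nrow(om)) {
    msg <- c(msg, "groups must have one entry per gene")
  }
  if (!all(object@groups %in% c("A", "B", "C", "D", "flat"))) {
    msg <- c(msg, "groups must be A/B/C/D/flat")
  }
  if (length(msg)) msg else TRUE
})
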