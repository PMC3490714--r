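#' @rdname DiurnalExperiment
#' @param x an object.
#' @export
setGeneric("arrayTime", function(x) standardGeneric("arrayTime"))

#' @rdname DiurnalExperiment
#' @export
setGeneric("arrayPhase", function(x) standardGeneric("arrayPhase"))

#' @describeIn DiurnalExperiment per-array sampling times (hours).
#' @export
setMethod("arrayTime", "DiurnalExperiment", function(x) {
  as.numeric(SummarizedExperiment::colData(x)$time_h)
})

#' @describeIn DiurnalExperiment per-array phase labels ("dark"/"light").
#' @export
setMethod("arrayPhase", "DiurnalExperiment", function(x) {
  as.character(SummarizedExperiment::colData(x)$phase)
})

#' Accessors for GGM network objects
#'
#' @param x a [GGMNetwork-class] (or, for `eta0`/`kappaNull`, a
#'   [MixtureFit-class]).
#' @return `pcor`: the partial-correlation matrix; `edges`: the selected edge
#'   data.frame; `mixtureFit`: the [MixtureFit-class]; `shrinkageLambda`: the
#'   shrinkage intensity; `eta0`, `kappaNull`: the fitted mixture parameters.
#' @name ggm-accessors
NULL

#' @rdname ggm-accessors
#' @export
setGeneric("pcor", function(x) standardGeneric("pcor"))

#' @rdname ggm-accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname ggm-accessors
#' @export
setGeneric("mixtureFit", function(x) standardGeneric("mixtureFit"))

#' @rdname ggm-accessors
#' @export
setGeneric("shrinkageLambda", function(x) standardGeneric("shrinkageLambda"))

#' @rdname ggm-accessors
#' @export
setGeneric("eta0", function(x) standardGeneric("eta0"))

#' @rdname ggm-accessors
#' @export
setGeneric("kappaNull", function(x) standardGeneric("kappaNull"))

#' @rdname ggm-accessors
#' @export
setMethod("pcor", "GGMNetwork", function(x) x@pcor)

#' @rdname ggm-accessors
#' @export
setMethod("edges", "GGMNetwork", function(x) x@edges)

#' @rdname ggm-accessors
#' @export
setMethod("mixtureFit", "GGMNetwork", function(x) x@mixture)

#' @rdname ggm-accessors
#' @export
setMethod("shrinkageLambda", "GGMNetwork", function(x) x@lambda)

#' @rdname ggm-accessors
#' @export
setMethod("eta0", "MixtureFit", function(x) x@eta0)

#' @rdname ggm-accessors
#' @export
setMethod("kappaNull", "MixtureFit", function(x) x@kappa)

#' @rdname ggm-accessors
#' @export
setMethod("eta0", "GGMNetwork", function(x) x@mixture@eta0)

#' @rdname ggm-accessors
#' @export
setMethod("kappaNull", "GGMNetwork", function(x) x@mixture@kappa)

#' Accessors for planted ground truth
#'
#' @param x a [GGMGroundTruth-class].
#' @return `trueEdges`: data.frame of planted edges with implied partial
#'   correlations; `truePcor`: the implied partial-correlation matrix;
#'   `geneGroups`: the planted diurnal response-group per gene.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
setGeneric("trueEdges", function(x) standardGeneric("trueEdges"))

#' @rdname truth-accessors
#' @export
setGeneric("truePcor", function(x) standardGeneric("truePcor"))

#' @rdname truth-accessors
#' @export
setGeneric("geneGroups", function(x) standardGeneric("geneGroups"))

#' @rdname truth-accessors
#' @export
setMethod("trueEdges", "GGMGroundTruth", function(x) x@trueEdges)

#' @rdname truth-accessors
#' @export
setMethod("truePcor", "GGMGroundTruth", function(x) x@truePcor)

#' @rdname truth-accessors
#' @export
setMethod("geneGroups", "GGMGroundTruth", function(x) {
  setNames(x@groups, rownames(x@precision))
})

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit: null/alternative mixture over partial correlations\n")
  cat(sprintf("  eta0 (null proportion): %.4f\n", object@eta0))
  cat(sprintf("  kappa (null df):        %.2f\n", object@kappa))
  cat(sprintf("  log-likelihood:         %.2f  (n = %d)\n",
              object@logLik, object@n))
})

setMethod("show", "GGMNetwork", function(object) {
  cat(sprintf("GGMNetwork: %d genes, %d selected edges (q <= %g)\n",
              nrow(object@pcor), nrow(object@edges), object@qThreshold))
  cat(sprintf("  shrinkage lambda: %.4f | eta0: %.4f | kappa: %.2f\n",
              object@lambda, object@mixture@eta0, object@mixture@kappa))
})

setMethod("show", "GGMGroundTruth", function(object) {
  cat(sprintf("GGMGroundTruth: %d genes, %d true edges\n",
              nrow(object@precision), nrow(object@trueEdges)))
  if (nrow(object@trueEdges)) {
    cat(sprintf("  |true pcor| range on edges: [%.3f, %.3f]\n",
                min(abs(object@trueEdges$pcor)),
                max(abs(object@trueEdges$pcor))))
  }
  cat("  groups: ", paste(sprintf("%s:%d", names(table(object@groups)),
                                  table(object@groups)), collapse = " "), "\n")
})

setMethod("show", "SplineBasis", function(object) {
  cat(sprintf("SplineBasis: %d arrays, df = %d (+ intercept)\n",
              nrow(object@design), object@df))
})
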