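# End-to-end pipeline driver tying the stages together with one validated
# configuration object.

#' Pipeline configuration
#'
#' @param deQThreshold q-value cutoff for time-course significance
#'   (default 0.01).
#' @param edgeQThreshold q-value cutoff for network edges (default 0.05).
#' @param kmeansK number of k-means clusters (default 30).
#' @param splineDf spline basis dimension (default 3).
#' @param deNPerm permutations for the time-course test (default 1000).
#' @param rankingConfidence one-sided confidence of the candidate cutoff
#'   (default 0.975).
#' @param inputScale `"log2"` (values already log2; default) or
#'   `"linear"` (values are log2-transformed on entry).
#' @param seed RNG seed used by every stochastic stage.
#' @return a validated configuration list of class `"starchnet_config"`.
#' @export
pipelineConfig <- function(deQThreshold = 0.01, edgeQThreshold = 0.05,
                           kmeansK = 30L, splineDf = 3L, deNPerm = 1000L,
                           rankingConfidence = 0.975,
                           inputScale = c("log2", "linear"), seed = NULL) {
  inputScale <- match.arg(inputScale)
  stopIfNot(deQThreshold > 0 && deQThreshold < 1,
            "'deQThreshold' must be in (0,1)")
  stopIfNot(edgeQThreshold > 0 && edgeQThreshold < 1,
            "'edgeQThreshold' must be in (0,1)")
  stopIfNot(rankingConfidence > 0.5 && rankingConfidence < 1,
            "'rankingConfidence' must be in (0.5, 1)")
  stopIfNot(kmeansK >= 1L, "'kmeansK' must be at least 1")
  stopIfNot(splineDf >= 1L, "'splineDf' must be at least 1")
  structure(list(deQThreshold = deQThreshold,
                 edgeQThreshold = edgeQThreshold,
                 kmeansK = as.integer(kmeansK),
                 splineDf = as.integer(splineDf),
                 deNPerm = as.integer(deNPerm),
                 rankingConfidence = rankingConfidence,
                 inputScale = inputScale, seed = seed),
            class = "starchnet_config")
}

#' Run the full network-inference pipeline
#'
#' Time-course significance testing, clustering with response-group
#' assignment, GGM network inference on the significant genes, topology
#' summaries, the first-neighbour subnetwork around the target genes, and
#' (when a compendium is supplied) the candidate-regulator report.
#'
#' @param x a [DiurnalExperiment-class].
#' @param annotation annotation data.frame (see [readAnnotation()]).
#' @param config a [pipelineConfig()] object.
#' @param compendium optional compendium data.frame for candidate ranking.
#' @param bindingTable optional binding-site table.
#' @return list with elements `de`, `clusters`, `network`, `graph`,
#'   `degrees`, `edgeTypes`, `subnetwork`, `candidates` (NULL without a
#'   compendium) and `config`.
#' @export
runStarchPipeline <- function(x, annotation, config = pipelineConfig(),
                              compendium = NULL, bindingTable = NULL) {
  stopifnot(is(x, "DiurnalExperiment"), inherits(config, "starchnet_config"))
  annotation <- validateAnnotation(annotation, geneIds = rownames(x))
  if (config$inputScale == "linear") {
    m <- SummarizedExperiment::assay(x, "exprs")
    if (any(m <= 0)) stop("linear-scale input must be positive for log2")
    x <- DiurnalExperiment(log2(m), arrayTime(x), arrayPhase(x))
  }
  de <- deTest(x, df = config$splineDf, nPerm = config$deNPerm,
               qThreshold = config$deQThreshold, seed = config$seed)
  sig <- de$gene_id[de$significant]
  if (length(sig) < 3L) {
    warning("fewer than 3 significant genes; using all genes downstream")
    sig <- de$gene_id
  }
  xs <- x[sig, ]
  clusters <- clusterGenes(xs, k = min(config$kmeansK, length(sig)),
                           seed = config$seed)
  network <- ggmNetwork(xs, qThreshold = config$edgeQThreshold)
  ann <- annotation[annotation$gene_id %in% sig, , drop = FALSE]
  graph <- buildAnnotatedGraph(network, annotation = ann, strict = FALSE)
  degrees <- degreeTable(graph)
  edgeTypes <- classifyEdges(graph)
  targets <- ann$gene_id[ann$role == "target"]
  subnetwork <- suppressWarnings(firstNeighborSubnetwork(graph, targets))
  candidates <- NULL
  if (!is.null(compendium) && nrow(edges(network))) {
    types <- edgeTypes$types
    ends <- igraph::ends(graph, igraph::E(graph))
    rt <- which(types == "regulator-target")
    if (length(rt)) {
      role <- igraph::vertex_attr(graph, "role")
      names(role) <- igraph::V(graph)$name
      pairs <- data.frame(
        regulator_gene = ifelse(role[ends[rt, 1L]] == "target",
                                ends[rt, 2L], ends[rt, 1L]),
        target_gene = ifelse(role[ends[rt, 1L]] == "target",
                             ends[rt, 1L], ends[rt, 2L]),
        stringsAsFactors = FALSE)
      keep <- paste(pairs$regulator_gene, pairs$target_gene) %in%
        paste(compendium$regulator_gene, compendium$target_gene)
      if (any(keep)) {
        candidates <- candidateReport(pairs[keep, , drop = FALSE],
                                      compendium, x = x,
                                      bindingTable = bindingTable,
                                      confidence = config$rankingConfidence)
      }
    }
  }
  list(de = de, clusters = clusters, network = network, graph = graph,
       degrees = degrees, edgeTypes = edgeTypes, subnetwork = subnetwork,
       candidates = candidates, config = config)
}
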