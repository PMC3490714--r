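# Topology of the inferred network: annotated graph construction, degree
# distribution and hub detection, first-neighbour subnetwork extraction
# around the target (starch) genes, edge typing by gene role, and overlap
# between alternative network reconstructions.

#' Build an annotated undirected graph from a selected edge set
#'
#' @param x a [GGMNetwork-class] or an edge data.frame (`gene_a`, `gene_b`,
#'   optionally `pcor`, `p_value`, `q_value`, `sign`).
#' @param annotation optional annotation data.frame (see [readAnnotation()])
#'   supplying node `role`/`family` attributes; genes missing from it get
#'   role `"unknown"` unless `strict = TRUE`.
#' @param includeIsolated when an annotation is given, also add annotated
#'   genes that have no selected edge as isolated nodes (default `FALSE`:
#'   the graph contains exactly the connected genes).
#' @param strict error on unannotated endpoints (default `TRUE` when an
#'   annotation is supplied).
#' @return an `igraph` undirected simple graph with vertex attributes
#'   `role`, `family` and edge attributes `pcor`, `q_value`, `sign`.
#' @export
buildAnnotatedGraph <- function(x, annotation = NULL,
                                includeIsolated = FALSE,
                                strict = !is.null(annotation)) {
  ed <- normalizeEdges(x)
  nodes <- sort(unique(c(ed$gene_a, ed$gene_b)))
  if (!is.null(annotation)) {
    annotation <- validateAnnotation(annotation)
    if (includeIsolated) nodes <- sort(unique(c(nodes, annotation$gene_id)))
    role <- annotation$role[match(nodes, annotation$gene_id)]
    family <- annotation$family[match(nodes, annotation$gene_id)]
    if (anyNA(role)) {
      if (strict) {
        stop(sprintf("unannotated endpoint(s): %s",
                     paste(nodes[is.na(role)], collapse = ", ")))
      }
      role[is.na(role)] <- "unknown"
    }
    family[is.na(family)] <- ""
  } else {
    role <- rep("unknown", length(nodes))
    family <- rep("", length(nodes))
  }
  vdf <- data.frame(name = nodes, role = role, family = family,
                    stringsAsFactors = FALSE)
  edf <- data.frame(from = ed$gene_a, to = ed$gene_b,
                    pcor = if (is.null(ed$pcor)) NA_real_ else ed$pcor,
                    q_value = if (is.null(ed$q_value)) NA_real_ else ed$q_value,
                    sign = if (is.null(ed$sign)) 1L else ed$sign,
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  if (any(igraph::which_loop(g)) || any(igraph::which_multiple(g))) {
    stop("edge list contains self-loops or duplicate edges")
  }
  g
}

#' Node degrees, degree histogram and hub of a network
#'
#' @param g an igraph graph (see [buildAnnotatedGraph()]).
#' @return list with `table` (data.frame `node`, `role`, `degree`, sorted by
#'   decreasing degree then name), `histogram` (counts per degree value),
#'   `hub` (maximum-degree node, lexicographic tie-break) and `tiedHubs`
#'   (all nodes attaining the maximum degree).
#' @export
degreeTable <- function(g) {
  if (igraph::vcount(g) == 0L) {
    return(list(table = data.frame(node = character(), role = character(),
                                   degree = integer()),
                histogram = table(integer()), hub = NA_character_,
                tiedHubs = character()))
  }
  deg <- igraph::degree(g)
  role <- igraph::vertex_attr(g, "role")
  if (is.null(role)) role <- rep("unknown", length(deg))
  tab <- data.frame(node = names(deg), role = role, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$degree, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  tied <- sort(tab$node[tab$degree == max(tab$degree)])
  list(table = tab, histogram = table(tab$degree), hub = tied[1L],
       tiedHubs = tied)
}

#' First-neighbour subnetwork around seed genes
#'
#' Induced subgraph on the seeds plus every node adjacent to a seed.  Seeds
#' without edges are retained as isolated nodes; seeds absent from the graph
#' are skipped with a warning.
#'
#' @param g an igraph graph.
#' @param seeds character vector of seed gene ids (typically the target /
#'   starch metabolic genes).
#' @return an igraph graph, an induced subgraph of `g`.
#' @export
firstNeighborSubnetwork <- function(g, seeds) {
  seeds <- unique(as.character(seeds))
  present <- seeds %in% igraph::V(g)$name
  if (any(!present)) {
    warning(sprintf("seed(s) not in graph, skipped: %s",
                    paste(seeds[!present], collapse = ", ")))
  }
  seeds <- seeds[present]
  if (!length(seeds)) {
    return(igraph::induced_subgraph(g, integer(0)))
  }
  nb <- unique(unlist(lapply(
    igraph::adjacent_vertices(g, seeds), function(v) v$name)))
  igraph::induced_subgraph(g, unique(c(seeds, nb)))
}

edgeTypeOf <- function(roleA, roleB) {
  regA <- roleA %in% c("regulator", "clock")
  regB <- roleB %in% c("regulator", "clock")
  ifelse(regA & regB, "regulator-regulator",
         ifelse(!regA & !regB, "target-target", "regulator-target"))
}

#' Classify network edges by the roles of their endpoints
#'
#' Clock genes count as regulators, so the three types are
#' regulator-regulator (TF/clock internal), regulator-target and
#' target-target; every edge belongs to exactly one type.
#'
#' @param g an igraph graph with a `role` vertex attribute, or an edge
#'   data.frame combined with `annotation`.
#' @param annotation annotation data.frame, required when `g` lacks roles.
#' @return list with `counts` (named integer vector over the three types,
#'   summing to the edge count) and `types` (per-edge type, in `g`'s edge
#'   order).
#' @export
classifyEdges <- function(g, annotation = NULL) {
  if (!igraph::is_igraph(g)) {
    g <- buildAnnotatedGraph(g, annotation = annotation)
  }
  role <- igraph::vertex_attr(g, "role")
  if (is.null(role) || any(role == "unknown")) {
    if (is.null(annotation)) stop("unannotated endpoint: supply 'annotation'")
    annotation <- validateAnnotation(annotation)
    role <- annotation$role[match(igraph::V(g)$name, annotation$gene_id)]
    if (anyNA(role)) stop("unannotated endpoint in graph")
  }
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  types <- if (nrow(ends)) {
    edgeTypeOf(role[ends[, 1L]], role[ends[, 2L]])
  } else character()
  lv <- c("regulator-regulator", "regulator-target", "target-target")
  counts <- table(factor(types, levels = lv))
  list(counts = setNames(as.integer(counts), lv), types = types)
}

edgeKeys <- function(g) {
  ends <- igraph::ends(g, igraph::E(g))
  if (!nrow(ends)) return(character())
  canonicalPairs(ends[, 1L], ends[, 2L])$key
}

#' Edge overlap between two networks
#'
#' Fraction of the reference graph's edges (overall and per role-typed
#' class) that also occur in a comparison graph, the summary used to gauge
#' robustness of a network against reconstruction from an expanded gene set.
#'
#' @param g1 reference igraph graph (with `role` vertex attributes for the
#'   per-type breakdown).
#' @param g2 comparison igraph graph.
#' @return data.frame with columns `type`, `n_reference`, `n_shared`,
#'   `fraction`; the first row is the overall summary.
#' @export
edgeOverlap <- function(g1, g2) {
  k1 <- edgeKeys(g1)
  k2 <- edgeKeys(g2)
  shared <- k1 %in% k2
  types <- tryCatch(classifyEdges(g1)$types,
                    error = function(e) rep("untyped", length(k1)))
  out <- data.frame(type = "all", n_reference = length(k1),
                    n_shared = sum(shared),
                    fraction = if (length(k1)) mean(shared) else NA_real_,
                    stringsAsFactors = FALSE)
  for (tp in unique(types)) {
    sel <- types == tp
    out <- rbind(out, data.frame(
      type = tp, n_reference = sum(sel), n_shared = sum(shared[sel]),
      fraction = if (any(sel)) mean(shared[sel]) else NA_real_))
  }
  rownames(out) <- NULL
  out
}
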