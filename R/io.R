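# Readers and writers for the pipeline's tab-separated file formats.
# One dialect throughout: UTF-8, tab-separated, "." decimal, full-precision
# ("%.17g") numbers so every writer/reader pair is a lossless round trip.

readTsv <- function(path, what = "file") {
  if (!file.exists(path)) stop(sprintf("%s not found: %s", what, path))
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) != 1L) {
    stop(sprintf("ragged rows in %s: rows have %s fields", path,
                 paste(unique(nf), collapse = "/")))
  }
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read and write a diurnal expression matrix
#'
#' The matrix file is TSV with one row per gene: the first column holds gene
#' identifiers and the header names the arrays.  Array metadata (columns
#' `array_id`, `time_h`, `phase`) comes from a sidecar TSV or a data.frame.
#'
#' @param path matrix TSV path.
#' @param metadata sidecar metadata: a path or a data.frame with columns
#'   `array_id`, `time_h`, `phase`.
#' @return [readExpressionMatrix()]: a [DiurnalExperiment-class].
#' @examples
#' de <- simulateDiurnalMatrix(makeSparseGGM(5, 0.2, 0.3, seed = 1), seed = 1)
#' tf <- tempfile(fileext = ".tsv")
#' writeExpressionMatrix(de, tf)
#' de2 <- readExpressionMatrix(tf)
#' stopifnot(identical(assay(de), assay(de2)))
#' @export
readExpressionMatrix <- function(path, metadata = paste0(path, ".meta")) {
  tab <- readTsv(path, "expression matrix")
  if (ncol(tab) < 3L) stop("fewer than 2 arrays in expression matrix")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene id in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  vals <- tab[, -1L, drop = FALSE]
  num <- vapply(vals, function(col) {
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(vals)))
  num <- matrix(num, nrow = nrow(tab),
                dimnames = list(ids, colnames(tab)[-1L]))
  if (anyNA(num)) stop(sprintf("non-numeric expression values in %s", path))
  meta <- if (is.character(metadata)) readTsv(metadata, "array metadata")
          else as.data.frame(metadata)
  need <- c("array_id", "time_h", "phase")
  if (!all(need %in% colnames(meta))) {
    stop("array metadata must have columns array_id, time_h, phase")
  }
  idx <- match(colnames(num), meta$array_id)
  if (anyNA(idx)) {
    stop(sprintf("arrays missing from metadata: %s",
                 paste(colnames(num)[is.na(idx)], collapse = ", ")))
  }
  DiurnalExperiment(num, timeH = as.numeric(meta$time_h[idx]),
                    phase = as.character(meta$phase[idx]))
}

#' @rdname readExpressionMatrix
#' @param x a [DiurnalExperiment-class].
#' @param geneColumn header label of the gene-id column on output.
#' @export
writeExpressionMatrix <- function(x, path, metadata = paste0(path, ".meta"),
                                  geneColumn = "gene_id") {
  stopifnot(is(x, "DiurnalExperiment"))
  m <- SummarizedExperiment::assay(x, "exprs")
  header <- paste(c(geneColumn, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmtNum(m[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path, useBytes = TRUE)
  metaTab <- data.frame(array_id = colnames(m), time_h = fmtNum(arrayTime(x)),
                        phase = arrayPhase(x))
  utils::write.table(metaTab, metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and validate a gene annotation table
#'
#' The annotation assigns every gene a `role` — `"target"` (starch metabolic
#' gene), `"regulator"` (transcription factor) or `"clock"` — and a free-text
#' regulator `family` (empty allowed for targets).
#'
#' @param path TSV with columns `gene_id`, `role`, `family`.
#' @param geneIds optional vector of expression-matrix gene ids; when given,
#'   a warning reports annotation coverage if some genes are unannotated.
#' @return data.frame with columns `gene_id`, `role`, `family`.
#' @export
readAnnotation <- function(path, geneIds = NULL) {
  tab <- readTsv(path, "annotation")
  validateAnnotation(tab, geneIds = geneIds)
}

#' @rdname readAnnotation
#' @param annotation a data.frame to validate in place of a file.
#' @export
validateAnnotation <- function(annotation, geneIds = NULL) {
  need <- c("gene_id", "role", "family")
  if (!all(need %in% colnames(annotation))) {
    stop("annotation must have columns gene_id, role, family")
  }
  annotation <- as.data.frame(annotation)[need]
  annotation$gene_id <- as.character(annotation$gene_id)
  annotation$role <- as.character(annotation$role)
  annotation$family <- as.character(annotation$family)
  annotation$family[is.na(annotation$family)] <- ""
  bad <- which(!annotation$role %in% c("target", "regulator", "clock"))
  if (length(bad)) {
    stop(sprintf("unknown role '%s' for gene '%s' (row %d)",
                 annotation$role[bad[1L]], annotation$gene_id[bad[1L]],
                 bad[1L]))
  }
  if (anyDuplicated(annotation$gene_id)) {
    stop(sprintf("duplicate gene id in annotation: %s",
                 paste(unique(annotation$gene_id[
                   duplicated(annotation$gene_id)]), collapse = ", ")))
  }
  if (!is.null(geneIds)) {
    miss <- setdiff(geneIds, annotation$gene_id)
    if (length(miss)) {
      warning(sprintf(
        "annotation covers %d of %d matrix genes (%d unannotated)",
        length(geneIds) - length(miss), length(geneIds), length(miss)))
    }
  }
  annotation
}

#' Read a binding-site support table
#'
#' Presence/absence of a transcription-factor family's binding site in a
#' target gene's promoter, keyed by (`family`, `target_gene`); `present` is
#' `Y`/`N`, with an optional `site_offsets` column.
#'
#' @param path TSV path.
#' @return data.frame with columns `family`, `target_gene`, `present` (and
#'   `site_offsets` if present in the file).
#' @export
readBindingSites <- function(path) {
  tab <- readTsv(path, "binding-site table")
  need <- c("family", "target_gene", "present")
  if (!all(need %in% colnames(tab))) {
    stop("binding table must have columns family, target_gene, present")
  }
  if (!all(tab$present %in% c("Y", "N"))) {
    stop("binding 'present' must be Y or N")
  }
  tab
}

#' Read a condition-independent co-expression compendium
#'
#' One row per (regulator, target) pair with a compendium-wide correlation,
#' emulating a database of weighted Pearson correlations computed over many
#' independent experiments.
#'
#' @param path TSV with columns `regulator_gene`, `target_gene`,
#'   `correlation` and optionally `family`.
#' @return validated data.frame.
#' @export
readCompendium <- function(path) {
  tab <- readTsv(path, "compendium")
  need <- c("regulator_gene", "target_gene", "correlation")
  if (!all(need %in% colnames(tab))) {
    stop("compendium must have columns regulator_gene, target_gene, correlation")
  }
  tab$correlation <- as.numeric(tab$correlation)
  if (anyNA(tab$correlation) || any(!is.finite(tab$correlation))) {
    stop("compendium correlations must be finite numbers")
  }
  if (any(abs(tab$correlation) > 1)) {
    stop("compendium correlations must lie in [-1, 1]")
  }
  key <- paste(tab$regulator_gene, tab$target_gene)
  if (anyDuplicated(key)) stop("duplicate (regulator, target) pair in compendium")
  tab
}

#' Read a morphology measurement table
#'
#' @param path TSV with columns `object_id`, `line_label`, `object_class`
#'   (`chloroplast`/`granule`), `area`, `perimeter`, `width`, `height` and,
#'   for chloroplast rows, `granule_count`.
#' @return validated data.frame.
#' @export
readMorphology <- function(path) {
  tab <- readTsv(path, "morphology table")
  need <- c("object_id", "line_label", "object_class", "area", "perimeter")
  if (!all(need %in% colnames(tab))) {
    stop("morphology table must have columns object_id, line_label, object_class, area, perimeter")
  }
  if (!all(tab$object_class %in% c("chloroplast", "granule"))) {
    stop("object_class must be 'chloroplast' or 'granule'")
  }
  if (any(tab$area <= 0) || any(tab$perimeter <= 0)) {
    stop("area and perimeter must be positive")
  }
  if ("granule_count" %in% colnames(tab)) {
    gc <- tab$granule_count[!is.na(tab$granule_count)]
    if (any(gc < 0) || any(gc != round(gc))) {
      stop("granule_count must be a non-negative integer")
    }
  }
  tab
}

normalizeEdges <- function(x) {
  ed <- if (is(x, "GGMNetwork")) x@edges else as.data.frame(x)
  if (nrow(ed) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      pcor = numeric(), p_value = numeric(),
                      q_value = numeric(), sign = integer()))
  }
  cp <- canonicalPairs(as.character(ed$gene_a), as.character(ed$gene_b))
  ed$gene_a <- cp$a
  ed$gene_b <- cp$b
  if (is.null(ed$sign)) ed$sign <- ifelse(ed$pcor >= 0, 1L, -1L)
  ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
}

#' Write and read network edge lists
#'
#' Serialises a selected edge set as full-precision TSV, Cytoscape SIF
#' (`source<TAB>relation<TAB>target`, relation `pos`/`neg` by the sign of the
#' partial correlation) or GraphML (with node `role`/`family` attributes when
#' an annotation is supplied).  Endpoints are stored lexicographically
#' ordered so undirected edges have a canonical, byte-reproducible form.
#'
#' @param x a [GGMNetwork-class] or an edge data.frame with columns
#'   `gene_a`, `gene_b`, `pcor`, `p_value`, `q_value`.
#' @param path output path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @param annotation optional annotation data.frame (see [readAnnotation()])
#'   used to attach node attributes in GraphML output.
#' @return `writeEdgeList()` returns `path` invisibly; `readEdgeList()`
#'   returns an edge data.frame.
#' @export
writeEdgeList <- function(x, path, format = c("tsv", "sif", "graphml"),
                          annotation = NULL) {
  format <- match.arg(format)
  ed <- normalizeEdges(x)
  if (format == "tsv") {
    header <- "gene_a\tgene_b\tpcor\tp_value\tq_value\tsign"
    body <- if (nrow(ed)) {
      paste(ed$gene_a, ed$gene_b, fmtNum(ed$pcor), fmtNum(ed$p_value),
            fmtNum(ed$q_value), ed$sign, sep = "\t")
    } else character()
    writeLines(c(header, body), path, useBytes = TRUE)
  } else if (format == "sif") {
    lines <- if (nrow(ed)) {
      paste(ed$gene_a, ifelse(ed$sign >= 0, "pos", "neg"), ed$gene_b,
            sep = "\t")
    } else character()
    writeLines(lines, path, useBytes = TRUE)
  } else {
    g <- buildAnnotatedGraph(ed, annotation = annotation, strict = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- readTsv(path, "edge list")
    need <- c("gene_a", "gene_b", "pcor", "p_value", "q_value", "sign")
    if (!all(need %in% colnames(tab))) {
      stop("edge TSV must have columns gene_a, gene_b, pcor, p_value, q_value, sign")
    }
    return(normalizeEdges(tab))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(normalizeEdges(data.frame(gene_a = character(),
                                     gene_b = character(), pcor = numeric())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("malformed SIF line")
  rel <- vapply(parts, `[[`, character(1L), 2L)
  if (!all(rel %in% c("pos", "neg"))) stop("SIF relation must be pos or neg")
  sgn <- ifelse(rel == "pos", 1L, -1L)
  normalizeEdges(data.frame(gene_a = vapply(parts, `[[`, character(1L), 1L),
                            gene_b = vapply(parts, `[[`, character(1L), 3L),
                            pcor = as.numeric(sgn), p_value = NA_real_,
                            q_value = NA_real_, sign = sgn))
}
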