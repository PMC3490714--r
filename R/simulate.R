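# Synthetic-data generators.  Every pipeline input can be produced with
# known ground truth: diurnal expression matrices whose residual dependence
# follows a planted sparse GGM (sampled on the study's 1/2/4/8/12-h
# dark+light grid), co-expression compendia with planted regulators, and
# morphology tables of random ellipses with line-specific granule-count
# distributions.  All generators are pure functions of (parameters, seed).

#' Plant a sparse graphical Gaussian model
#'
#' Draws a random sparse symmetric support (soft-capped node degree so edge
#' partial correlations stay near the requested magnitude), sets the
#' unit-diagonal precision matrix to `omega_ij = -sign * m` on the support,
#' and verifies positive definiteness, scaling the off-diagonal down (never
#' below two thirds of the request — beyond that the combination is deemed
#' infeasible) if the spectrum requires it.  With a unit diagonal the
#' implied partial correlation on every edge is exactly `sign * m`.
#'
#' @param p number of genes.
#' @param edgeDensity fraction of the `p (p - 1) / 2` pairs carrying an
#'   edge, in \[0, 1).
#' @param pcorMagnitude target absolute partial correlation on true edges,
#'   in (0, 0.9).
#' @param seed optional RNG seed (stored in the result).
#' @param maxDegree soft cap on node degree during support sampling.
#' @param groups per-gene diurnal shape labels (`"A"`, `"B"`, `"C"`, `"D"`,
#'   `"flat"`), recycled; default cycles A-D.
#' @param planted optional data.frame of planted regulator -> target pairs
#'   carried along for compendium generation.
#' @return a [GGMGroundTruth-class].
#' @examples
#' truth <- makeSparseGGM(20, 0.15, 0.3, seed = 1)
#' truth
#' @export
makeSparseGGM <- function(p, edgeDensity, pcorMagnitude, seed = NULL,
                          maxDegree = 4L, groups = NULL, planted = NULL) {
  p <- as.integer(p)
  stopIfNot(p >= 2L, "'p' must be at least 2")
  stopIfNot(edgeDensity >= 0 && edgeDensity < 1,
            "'edgeDensity' must lie in [0, 1)")
  nPairs <- p * (p - 1L) / 2
  nEdges <- round(edgeDensity * nPairs)
  if (nEdges > 0L) {
    stopIfNot(pcorMagnitude > 0 && pcorMagnitude < 0.9,
              "'pcorMagnitude' must lie in (0, 0.9)")
  }
  ids <- sprintf("G%03d", seq_len(p))
  withSeed(seed, {
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    deg <- integer(p)
    take <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      if (sum(take) == nEdges) break
      i <- pairs[k, 1L]
      j <- pairs[k, 2L]
      if (deg[i] < maxDegree && deg[j] < maxDegree) {
        take[k] <- TRUE
        deg[i] <- deg[i] + 1L
        deg[j] <- deg[j] + 1L
      }
    }
    # soft cap: fill up from the remaining pairs if the cap starved us
    if (sum(take) < nEdges) {
      extra <- which(!take)[seq_len(nEdges - sum(take))]
      take[extra] <- TRUE
    }
    sel <- pairs[take, , drop = FALSE]
    sgn <- sample(c(-1, 1), nrow(sel), replace = TRUE)
    m <- pcorMagnitude
    repeat {
      omega <- diag(p)
      if (nrow(sel)) {
        omega[sel] <- -sgn * m
        omega[sel[, c(2L, 1L), drop = FALSE]] <- -sgn * m
      }
      ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
      if (ev >= 0.02 || nEdges == 0L) break
      m <- m * 0.95
      if (m < pcorMagnitude * 2 / 3) {
        stop("infeasible magnitude/density combination: positive definiteness cannot be achieved")
      }
    }
    dimnames(omega) <- list(ids, ids)
    d <- sqrt(diag(omega))
    pcorM <- -omega / outer(d, d)
    diag(pcorM) <- 0
    ed <- if (nrow(sel)) {
      cp <- canonicalPairs(ids[sel[, 1L]], ids[sel[, 2L]])
      data.frame(gene_a = cp$a, gene_b = cp$b, pcor = pcorM[sel],
                 stringsAsFactors = FALSE)[order(cp$a, cp$b), ]
    } else {
      data.frame(gene_a = character(), gene_b = character(),
                 pcor = numeric())
    }
    rownames(ed) <- NULL
    if (is.null(groups)) groups <- c("A", "B", "C", "D")
    groups <- rep(as.character(groups), length.out = p)
    if (is.null(planted)) {
      planted <- data.frame(regulator_gene = character(),
                            target_gene = character())
    }
    new("GGMGroundTruth", precision = omega, truePcor = pcorM,
        trueEdges = ed, groups = groups, planted = planted,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

# diurnal mean profile for one response-group shape on the array grid
groupShape <- function(group, phase) {
  n <- length(phase)
  light <- as.numeric(phase == "light")
  firstLight <- which(phase[-n] == "dark" & phase[-1L] == "light") + 1L
  if (phase[1L] == "light" && phase[n] == "dark") {
    firstLight <- c(1L, firstLight)
  }
  bump <- numeric(n)
  bump[firstLight] <- 1
  switch(group,
         A = 1 - light,
         B = light,
         C = bump,
         D = -bump,
         flat = numeric(n),
         stop(sprintf("unknown group shape '%s'", group)))
}

#' Simulate a diurnal expression matrix from planted ground truth
#'
#' Each gene's profile is its response-group mean shape times `amplitude`,
#' plus multivariate normal residuals whose correlation across genes is the
#' one implied by the planted precision matrix (scaled by `noiseSd`).  The
#' default sampling grid copies the study design: arrays after 1, 2, 4, 8
#' and 12 hours of darkness and of light.
#'
#' @param truth a [GGMGroundTruth-class].
#' @param timepoints hours sampled within each phase (default
#'   `c(1, 2, 4, 8, 12)`).
#' @param phases phases sampled (default dark then light).
#' @param amplitude scale of the group mean shapes (default 1, in log2
#'   units).
#' @param noiseSd residual standard deviation per gene and array
#'   (default 0.25 log2 units).
#' @param nReplicates independent repeats of the full grid (default 1).
#' @param seed optional RNG seed.
#' @return a [DiurnalExperiment-class] with `p` genes and
#'   `length(timepoints) * length(phases) * nReplicates` arrays.
#' @export
simulateDiurnalMatrix <- function(truth, timepoints = c(1, 2, 4, 8, 12),
                                  phases = c("dark", "light"),
                                  amplitude = 1, noiseSd = 0.25,
                                  nReplicates = 1L, seed = NULL) {
  stopifnot(is(truth, "GGMGroundTruth"))
  phase1 <- rep(phases, each = length(timepoints))
  time1 <- rep(timepoints, times = length(phases))
  phase <- rep(phase1, nReplicates)
  timeH <- rep(time1, nReplicates)
  p <- nrow(truth@precision)
  n <- length(phase)
  shape1 <- vapply(truth@groups, function(g) groupShape(g, phase1),
                   numeric(length(phase1)))          # arrays x genes
  shapes <- do.call(cbind, rep(list(t(shape1)), nReplicates))
  Sigma <- solve(truth@precision)
  Sigma <- stats::cov2cor(Sigma)
  withSeed(seed, {
    resid <- t(MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)) * noiseSd
    vals <- amplitude * shapes + resid
    dimnames(vals) <- list(rownames(truth@precision),
                           sprintf("array%03d", seq_len(n)))
    DiurnalExperiment(vals, timeH = timeH, phase = phase)
  })
}

#' Generate a condition-independent co-expression compendium
#'
#' Planted regulator-target pairs receive correlations drawn from
#' `Normal(effect, noiseSd)`; decoy regulators receive `Normal(0, noiseSd)`
#' for every target.  All values are truncated to \[-1, 1\].  Families are
#' assigned round-robin over regulators, so a planted regulator shares its
#' family with decoys and the within-family rank is informative.
#'
#' @param planted data.frame with columns `regulator_gene`, `target_gene`,
#'   or a [GGMGroundTruth-class] carrying planted pairs.
#' @param nDecoys decoy regulators per target (default 40).
#' @param effect mean correlation of planted pairs, in (0, 1) (default 0.5).
#' @param noiseSd correlation noise (default 0.15).
#' @param nFamilies number of regulator families (default 8).
#' @param seed optional RNG seed.
#' @return compendium data.frame (`regulator_gene`, `target_gene`,
#'   `correlation`, `family`).
#' @export
makeCompendium <- function(planted, nDecoys = 40L, effect = 0.5,
                           noiseSd = 0.15, nFamilies = 8L, seed = NULL) {
  if (is(planted, "GGMGroundTruth")) planted <- planted@planted
  planted <- as.data.frame(planted)
  stopIfNot(nrow(planted) > 0L, "no planted regulator-target pairs")
  stopIfNot(effect > 0 && effect < 1, "'effect' must lie in (0, 1)")
  decoys <- if (nDecoys > 0L) sprintf("TFd%03d", seq_len(nDecoys))
            else character()
  regs <- unique(c(planted$regulator_gene, decoys))
  fams <- setNames(paste0("F", (seq_along(regs) - 1L) %% nFamilies + 1L),
                   regs)
  targets <- unique(planted$target_gene)
  withSeed(seed, {
    rows <- lapply(targets, function(tg) {
      pr <- planted$regulator_gene[planted$target_gene == tg]
      rr <- unique(c(pr, decoys))
      mu <- ifelse(rr %in% pr, effect, 0)
      data.frame(regulator_gene = rr, target_gene = tg,
                 correlation = pmin(1, pmax(-1, rnorm(length(rr), mu,
                                                      noiseSd))),
                 family = fams[rr], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Perimeter of an ellipse (Ramanujan's second approximation)
#'
#' `pi (a + b) (1 + 3h / (10 + sqrt(4 - 3h)))` with
#' `h = ((a - b) / (a + b))^2`; exact for circles and accurate to a few
#' parts per million at the axis ratios generated here.
#'
#' @param a,b semi-axes.
#' @return perimeter(s).
#' @export
ellipsePerimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

morphLineDefaults <- list(
  WT = list(chloroplastArea = 13.2, granuleArea = 0.54, axisRatio = 1.4,
            ratioSd = 0.15, areaSdLog = 0.3,
            countProbs = c(0.18, 0.25, 0.275, 0.16, 0.08, 0.035, 0.015,
                           0.005)),
  mutant = list(chloroplastArea = 9.24, granuleArea = 0.42, axisRatio = 1.9,
                ratioSd = 0.15, areaSdLog = 0.3,
                countProbs = c(0.03, 0.21, 0.254, 0.23, 0.17, 0.06, 0.03,
                               0.016)))

#' Generate a synthetic morphology table
#'
#' Objects are random ellipses: areas log-normal around a line-specific
#' mean, axis ratios log-normal around a line-specific shape, perimeters
#' from Ramanujan's approximation.  The default `"mutant"` line has a 30%
#' smaller mean area and a more elongated shape than `"WT"`, and a
#' granule-count distribution shifted toward more granules per chloroplast,
#' so planted group differences are recoverable by the Mann-Whitney
#' analysis.
#'
#' @param nObjects chloroplasts (and granules) generated per line.
#' @param lines named list of line parameter lists; entries override the
#'   built-in `WT`/`mutant` defaults.  Recognised fields:
#'   `chloroplastArea`, `granuleArea` (mean areas), `axisRatio`, `ratioSd`,
#'   `areaSdLog`, `countProbs` (granules-per-chloroplast distribution over
#'   counts `1..length(countProbs)`).
#' @param seed optional RNG seed.
#' @return morphology data.frame (see [readMorphology()]).
#' @export
makeMorphology <- function(nObjects = 200L, lines = NULL, seed = NULL) {
  if (is.null(lines)) {
    lines <- morphLineDefaults
  } else {
    lines <- lapply(setNames(names(lines), names(lines)), function(nm) {
      base <- if (nm %in% names(morphLineDefaults)) morphLineDefaults[[nm]]
              else morphLineDefaults$WT
      utils::modifyList(base, lines[[nm]])
    })
  }
  sampleEllipses <- function(n, meanArea, sdLog, ratio, ratioSd) {
    area <- exp(rnorm(n, log(meanArea) - sdLog^2 / 2, sdLog))
    q <- pmax(1, exp(rnorm(n, log(ratio), ratioSd)))
    a <- sqrt(area * q / pi)
    b <- sqrt(area / (q * pi))
    data.frame(area = area, perimeter = ellipsePerimeter(a, b),
               width = 2 * a, height = 2 * b)
  }
  withSeed(seed, {
    out <- lapply(names(lines), function(nm) {
      par <- lines[[nm]]
      ch <- sampleEllipses(nObjects, par$chloroplastArea, par$areaSdLog,
                           par$axisRatio, par$ratioSd)
      pr <- par$countProbs / sum(par$countProbs)
      ch$granule_count <- sample.int(length(pr), nObjects, replace = TRUE,
                                     prob = pr)
      ch$object_class <- "chloroplast"
      gr <- sampleEllipses(nObjects, par$granuleArea, par$areaSdLog,
                           par$axisRatio, par$ratioSd)
      gr$granule_count <- NA_integer_
      gr$object_class <- "granule"
      both <- rbind(ch, gr)
      both$line_label <- nm
      both
    })
    tab <- do.call(rbind, out)
    tab$object_id <- sprintf("obj%05d", seq_len(nrow(tab)))
    rownames(tab) <- NULL
    tab[, c("object_id", "line_label", "object_class", "area", "perimeter",
            "width", "height", "granule_count")]
  })
}
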