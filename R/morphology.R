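# Morphometric statistics for chloroplast / starch-granule measurements:
# the isoperimetric circularity shape descriptor, Mann-Whitney U tests
# (exact by full enumeration at small pooled sizes, normal approximation
# with tie and continuity corrections otherwise), relative mean ranks, and
# granule-count distribution summaries.

#' Circularity of a measured object
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect circle, approaching 0 for
#' elongated shapes.  Values may exceed 1 only through measurement noise
#' (the isoperimetric inequality forbids it for true shapes) and are capped
#' at 1, with a warning when the exceedance is material (> 1e-6).
#'
#' @param area,perimeter positive measurements (vectorised).
#' @return circularity values in (0, 1\].
#' @examples
#' circularity(pi, 2 * pi)  # unit circle -> 1
#' circularity(1, 4)        # unit square -> pi / 4
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0)) {
    stop("area and perimeter must be positive")
  }
  x <- 4 * pi * area / perimeter^2
  if (any(x > 1 + 1e-6)) {
    warning("circularity above 1 + 1e-6: inconsistent area/perimeter pairs")
  }
  pmin(x, 1)
}

rankSumU <- function(x, y) {
  ranks <- rank(c(x, y))           # midranks for ties
  nx <- length(x)
  sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
}

#' Mann-Whitney U test
#'
#' U is computed from midrank sums.  The exact two-sided p-value enumerates
#' every assignment of the pooled values to the two groups and is the
#' probability of `|U - nx*ny/2|` at least as large as observed (a
#' symmetric definition that is robust to ties); it is used when
#' `nx + ny <= exactMaxN` under `mode = "auto"`.  Otherwise the normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used.
#'
#' @param x,y numeric samples (both nonempty).
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @param exactMaxN pooled-size limit for the exact enumeration in `auto`
#'   mode (default 12).
#' @return list with `U` (for sample `x`), `p` (two-sided) and `method`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$p  # 2/20
#' @export
mannWhitneyU <- function(x, y, mode = c("auto", "exact", "approx"),
                         exactMaxN = 12L) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  nx <- length(x)
  ny <- length(y)
  N <- nx + ny
  U <- rankSumU(x, y)
  mu <- nx * ny / 2
  if (mode == "auto") mode <- if (N <= exactMaxN) "exact" else "approx"
  if (mode == "exact") {
    if (choose(N, nx) > 5e5) stop("pooled sample too large for exact mode")
    ranks <- rank(c(x, y))
    combs <- combn(N, nx)
    Uperm <- colSums(matrix(ranks[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(Uperm - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = p, method = "exact"))
  }
  pooled <- c(x, y)
  ties <- table(pooled)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(U = U, p = 1, method = "approx"))
  }
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-max(z, 0)))
  list(U = U, p = p, method = "approx")
}

#' Relative mean ranks of two samples
#'
#' Mean midrank of each group within the pooled ranking; the weighted sum
#' `meanRankX * nx + meanRankY * ny` equals `N (N + 1) / 2`.  With
#' `percent = TRUE` ranks are rescaled by `100 / (N + 1)` so that two
#' identical groups both score 50, the customary presentation alongside the
#' Mann-Whitney test.
#'
#' @param x,y numeric samples.
#' @param percent rescale to the 0-100 relative scale (default `FALSE`).
#' @return named numeric vector `c(mean_rank_x = , mean_rank_y = )`.
#' @export
relativeMeanRanks <- function(x, y, percent = FALSE) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ranks <- rank(c(x, y))
  nx <- length(x)
  out <- c(mean_rank_x = mean(ranks[seq_len(nx)]),
           mean_rank_y = mean(ranks[-seq_len(nx)]))
  if (percent) out <- out * 100 / (length(ranks) + 1)
  out
}

#' Granule-count distribution per line
#'
#' Normalised histogram of starch granules per chloroplast for each plant
#' line, the share of chloroplasts inside a count window, and (when areas
#' are available) the mean chloroplast area per granule count — the
#' size-versus-count relationship.
#'
#' @param morphology morphology data.frame (see [readMorphology()]); only
#'   `object_class == "chloroplast"` rows with a `granule_count` are used.
#'   Alternatively a numeric vector of counts with `line` supplied.
#' @param window integer window `c(lo, hi)` for the windowed share
#'   (default `c(2, 5)`).
#' @param line optional line labels when `morphology` is a plain vector.
#' @return list with `histogram` (proportions per line x count),
#'   `windowShare` (per line), `meanAreaByCount` (per line, or `NULL`).
#' @export
countDistribution <- function(morphology, window = c(2L, 5L), line = NULL) {
  if (is.data.frame(morphology)) {
    rows <- morphology$object_class == "chloroplast" &
      !is.na(morphology$granule_count)
    counts <- morphology$granule_count[rows]
    line <- morphology$line_label[rows]
    area <- morphology$area[rows]
  } else {
    counts <- as.numeric(morphology)
    if (is.null(line)) line <- rep("all", length(counts))
    area <- NULL
  }
  if (!length(counts)) stop("no granule counts present")
  lineF <- factor(line)
  countF <- factor(counts, levels = sort(unique(counts)))
  tab <- table(lineF, countF)
  hist <- prop.table(tab, margin = 1L)
  inWin <- counts >= window[1L] & counts <= window[2L]
  share <- tapply(inWin, lineF, mean)
  mab <- NULL
  if (!is.null(area)) {
    mab <- tapply(seq_along(area), lineF, function(i) {
      tapply(area[i], counts[i], mean)
    })
  }
  list(histogram = hist, windowShare = share, meanAreaByCount = mab)
}

#' Morphology comparison report
#'
#' For each non-reference line and measure, the relative mean ranks
#' (0-100 scale) of mutant versus reference and the two-sided Mann-Whitney
#' p-value, computed separately per object class; granule counts per
#' chloroplast are compared the same way.
#'
#' @param morphology morphology data.frame (see [readMorphology()]).
#' @param reference line label of the reference (wild-type) group.
#' @param measures measurement columns to compare.
#' @param mode passed to [mannWhitneyU()].
#' @return data.frame with columns `line`, `object_class`, `measure`,
#'   `n_line`, `n_reference`, `rank_line`, `rank_reference`, `p_value`.
#' @export
morphologyReport <- function(morphology, reference = "WT",
                             measures = c("area", "width", "height",
                                          "circularity"),
                             mode = "auto") {
  stopifnot(reference %in% morphology$line_label)
  if (!"circularity" %in% colnames(morphology) &&
      "circularity" %in% measures) {
    morphology$circularity <- circularity(morphology$area,
                                          morphology$perimeter)
  }
  lines <- setdiff(unique(morphology$line_label), reference)
  out <- list()
  for (cls in intersect(c("chloroplast", "granule"),
                        unique(morphology$object_class))) {
    sub <- morphology[morphology$object_class == cls, , drop = FALSE]
    vars <- intersect(measures, colnames(sub))
    if (cls == "chloroplast" && "granule_count" %in% colnames(sub)) {
      vars <- c(vars, "granule_count")
    }
    for (ln in lines) {
      for (v in vars) {
        a <- sub[[v]][sub$line_label == ln]
        b <- sub[[v]][sub$line_label == reference]
        a <- a[!is.na(a)]
        b <- b[!is.na(b)]
        if (!length(a) || !length(b)) next
        mw <- mannWhitneyU(a, b, mode = mode)
        rr <- relativeMeanRanks(a, b, percent = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          line = ln, object_class = cls, measure = v,
          n_line = length(a), n_reference = length(b),
          rank_line = unname(rr[1L]), rank_reference = unname(rr[2L]),
          p_value = mw$p, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
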