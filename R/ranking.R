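# Candidate-regulator refinement.  Regulator -> target edges from the GGM
# subnetwork are re-examined against a condition-independent co-expression
# compendium: regulators are ranked by their compendium correlation with the
# target, admitted when that correlation exceeds the upper one-sided normal
# confidence bound of the regulator-population correlations, filtered by a
# temporal-precedence rule on the diurnal profiles, and annotated with
# binding-site support.

#' Rank regulators of a target by compendium correlation
#'
#' Descending sort with competition ranking (ties share the smaller rank,
#' the next rank is skipped): overall rank among all rows for the target,
#' rank among regulator rows, and rank within each regulator family.
#'
#' @param compendium data.frame as returned by [readCompendium()] /
#'   [makeCompendium()]; a `family` column enables the within-family rank.
#' @param target target gene id.
#' @return data.frame sorted by decreasing correlation with columns
#'   `regulator_gene`, `family`, `correlation`, `rank_all_genes`,
#'   `rank_all_regulators`, `rank_in_family`, `family_size`.
#' @export
rankRegulators <- function(compendium, target) {
  tab <- compendium[compendium$target_gene == target, , drop = FALSE]
  if (!nrow(tab)) stop(sprintf("target '%s' absent from compendium", target))
  if (is.null(tab$family)) tab$family <- ""
  tab <- tab[order(-tab$correlation, tab$regulator_gene), , drop = FALSE]
  rk <- rank(-tab$correlation, ties.method = "min")
  out <- data.frame(regulator_gene = tab$regulator_gene,
                    family = tab$family, correlation = tab$correlation,
                    rank_all_genes = as.integer(rk),
                    rank_all_regulators = as.integer(rk),
                    rank_in_family = as.integer(ave(
                      -tab$correlation, tab$family,
                      FUN = function(z) rank(z, ties.method = "min"))),
                    family_size = as.integer(ave(
                      tab$correlation, tab$family, FUN = length)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-sided population cutoff for a candidate correlation
#'
#' The compendium correlations of all regulators with a target are treated
#' as a normal population; a candidate passes when its correlation exceeds
#' the population mean with the requested one-sided confidence, i.e.
#' `candidate > mean + t_(confidence, n-1) * sd`.  The candidate value
#' should not itself be part of `population` ([candidateReport()] applies
#' the cutoff leave-one-out).
#'
#' @param population numeric vector of regulator-target correlations
#'   (length >= 3, nonzero variance).
#' @param candidate candidate correlation value(s).
#' @param confidence one-sided confidence level in (0.5, 1), default 0.975.
#' @return logical, `TRUE` where the candidate passes.
#' @export
ttestCutoff <- function(population, candidate, confidence = 0.975) {
  population <- as.numeric(population)
  if (length(population) < 3L) stop("population must have at least 3 values")
  stopIfNot(confidence > 0.5 && confidence < 1,
            "'confidence' must be in (0.5, 1)")
  s <- sd(population)
  if (s == 0) stop("zero-variance population")
  cut <- mean(population) + qt(confidence, length(population) - 1L) * s
  candidate > cut
}

#' Hour-of-cycle coordinate
#'
#' Maps (`phase`, hours since the last transition) to an absolute hour of
#' the diurnal cycle: dark occupies `[0, darkHours)`, light
#' `[darkHours, period)`.
#'
#' @param timeH,phase,darkHours,period see [precedenceFilter()].
#' @return numeric hours in `[0, period)`.
#' @export
cycleHour <- function(timeH, phase, darkHours = 12, period = 24) {
  ifelse(phase == "dark", timeH, darkHours + timeH) %% period
}

# interpolate a profile onto an hourly circular grid
circularGrid <- function(y, hours, period = 24) {
  o <- order(hours)
  h <- hours[o]
  v <- y[o]
  ext <- c(h - period, h, h + period)
  vv <- rep(v, 3L)
  approx(ext, vv, xout = seq(0, period - 1), method = "linear",
         ties = mean)$y
}

#' Temporal-precedence filter for a regulator-target pair
#'
#' Estimates the signed circular lag of the regulator profile relative to
#' the target as the lag maximising the circular cross-correlation on an
#' hourly interpolated 24-h grid (shorter signed direction modulo the
#' cycle).  The pair passes when the regulator peaks at the same time or
#' earlier than the target.  Flat profiles pass with a warning.
#'
#' @param regProfile,targetProfile expression profiles on the same arrays.
#' @param timeH per-array hours since the last phase transition.
#' @param phase per-array `"dark"`/`"light"` labels.
#' @param darkHours length of the dark period in hours (default 12).
#' @param period cycle length in hours (default 24).
#' @return logical scalar with attribute `"lag"` (hours; positive = the
#'   regulator leads the target).
#' @examples
#' t <- rep(c(1, 2, 4, 8, 12), 2)
#' ph <- rep(c("dark", "light"), each = 5)
#' y <- sin(2 * pi * cycleHour(t, ph) / 24)
#' precedenceFilter(y, y, t, ph)  # identical profiles pass
#' @export
precedenceFilter <- function(regProfile, targetProfile, timeH, phase,
                             darkHours = 12, period = 24) {
  phase <- checkPhase(phase, length(regProfile))
  hours <- cycleHour(timeH, phase, darkHours, period)
  if (sd(regProfile) == 0 || sd(targetProfile) == 0) {
    warning("flat profile: precedence filter passes by default")
    return(structure(TRUE, lag = NA_real_))
  }
  rg <- circularGrid(regProfile, hours, period)
  tg <- circularGrid(targetProfile, hours, period)
  lags <- seq(-period / 2, period / 2 - 1)
  cc <- vapply(lags, function(l) {
    # delay the regulator by l hours; if it led the target by l, they align
    shifted <- rg[((seq_along(rg) - 1 - l) %% period) + 1]
    suppressWarnings(cor(shifted, tg))
  }, numeric(1L))
  cc[is.na(cc)] <- -Inf
  best <- lags[cc >= max(cc) - 1e-12]
  # ties: prefer the lag closest to zero, then the earlier (positive) one
  lag <- best[order(abs(best), -best)][1L]
  structure(lag >= 0, lag = lag)
}

#' Annotate a candidate report with binding-site support
#'
#' Joins the report against a (`family`, `target_gene`) keyed binding-site
#' table; `binding_support` is `"Y"`/`"N"` from the table and `NA` when the
#' pair is absent.
#'
#' @param report candidate report data.frame with columns `family` and
#'   `target_gene`.
#' @param bindingTable data.frame as from [readBindingSites()].
#' @return the report with a `binding_support` column.
#' @export
annotateBindingSupport <- function(report, bindingTable) {
  key <- paste(report$family, report$target_gene, sep = "\r")
  bkey <- paste(bindingTable$family, bindingTable$target_gene, sep = "\r")
  report$binding_support <- as.character(bindingTable$present[match(key, bkey)])
  report
}

#' Build a candidate-regulator report for regulator-target edges
#'
#' For every regulator -> target edge, looks up the compendium correlation
#' and ranks, applies the population cutoff ([ttestCutoff()]) and the
#' temporal-precedence filter ([precedenceFilter()]), and (optionally)
#' annotates binding-site support.
#'
#' @param pairs data.frame with columns `regulator_gene`, `target_gene`
#'   (e.g. the regulator-target edges of the starch subnetwork).
#' @param compendium compendium data.frame (see [readCompendium()]).
#' @param x optional [DiurnalExperiment-class] supplying diurnal profiles
#'   for the precedence filter (pairs with missing profiles pass with `NA`).
#' @param bindingTable optional binding-site table.
#' @param confidence one-sided confidence for the population cutoff.
#' @param population which correlations form the test population:
#'   `"regulators"` (all regulator rows for the target; default) or
#'   `"all"` (every compendium row for the target).
#' @return data.frame, one row per pair, with correlation, ranks, filter
#'   outcomes and `binding_support`.
#' @export
candidateReport <- function(pairs, compendium, x = NULL, bindingTable = NULL,
                            confidence = 0.975,
                            population = c("regulators", "all")) {
  population <- match.arg(population)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    tg <- as.character(pairs$target_gene[i])
    rg <- as.character(pairs$regulator_gene[i])
    rks <- rankRegulators(compendium, tg)
    j <- match(rg, rks$regulator_gene)
    if (is.na(j)) {
      stop(sprintf("pair (%s, %s) absent from compendium", rg, tg))
    }
    # leave-one-out: a candidate is never tested against statistics it
    # contaminates (at compendium scale, thousands of regulators, the
    # distinction vanishes; at synthetic scale it matters)
    pop <- rks$correlation[-j]
    passT <- ttestCutoff(pop, rks$correlation[j], confidence = confidence)
    passP <- NA
    if (!is.null(x) && all(c(rg, tg) %in% rownames(x))) {
      m <- SummarizedExperiment::assay(x, "exprs")
      passP <- as.logical(precedenceFilter(m[rg, ], m[tg, ], arrayTime(x),
                                           arrayPhase(x)))
    }
    data.frame(target_gene = tg, regulator_gene = rg, family = rks$family[j],
               correlation = rks$correlation[j],
               rank_all_genes = rks$rank_all_genes[j],
               rank_all_regulators = rks$rank_all_regulators[j],
               rank_in_family = rks$rank_in_family[j],
               family_size = rks$family_size[j],
               passes_ttest = passT, passes_precedence = passP,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report$binding_support <- NA_character_
  if (!is.null(bindingTable)) {
    report <- annotateBindingSupport(report, bindingTable)
  }
  report
}

#' Select final regulator candidates
#'
#' Keeps report rows that pass both the population cutoff and the
#' temporal-precedence filter (a missing precedence verdict counts as a
#' pass).  Binding support is retained as evidence but not required.
#'
#' @param report data.frame from [candidateReport()].
#' @return the filtered report.
#' @export
selectFinalCandidates <- function(report) {
  keep <- report$passes_ttest &
    (is.na(report$passes_precedence) | report$passes_precedence)
  out <- report[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
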