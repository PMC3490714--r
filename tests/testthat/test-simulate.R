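test_that("planted GGM support, magnitudes and determinism behave", {
  t0 <- makeSparseGGM(10, 0, 0.3, seed = 1)
  expect_equal(truePcor(t0), matrix(0, 10, 10), ignore_attr = TRUE)
  expect_equal(nrow(trueEdges(t0)), 0L)
  t1 <- makeSparseGGM(20, 0.15, 0.3, seed = 2)
  ed <- trueEdges(t1)
  expect_equal(nrow(ed), round(0.15 * choose(20, 2)))
  expect_true(all(abs(ed$pcor) >= 0.2 & abs(ed$pcor) <= 0.4))
  # support is exactly the nonzero off-diagonal pattern of the precision
  om <- t1@precision
  diag(om) <- 0
  ids <- rownames(om)
  nz <- which(om != 0 & upper.tri(om), arr.ind = TRUE)
  expect_setequal(paste(ids[nz[, 1]], ids[nz[, 2]]),
                  paste(ed$gene_a, ed$gene_b))
  ev <- eigen(t1@precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  t1b <- makeSparseGGM(20, 0.15, 0.3, seed = 2)
  expect_identical(t1@precision, t1b@precision)
  expect_identical(trueEdges(t1), trueEdges(t1b))
  expect_error(makeSparseGGM(10, 0.5, 0.85), "infeasible")
})

test_that("diurnal simulation reproduces the designed mean structure", {
  t1 <- makeSparseGGM(8, 0, 0.3, seed = 3,
                      groups = c("A", "B", "C", "D", "flat", "A", "B", "flat"))
  de <- simulateDiurnalMatrix(t1, amplitude = 2, noiseSd = 0.01, seed = 3)
  expect_s4_class(de, "DiurnalExperiment")
  expect_equal(dim(de), c(8L, 10L))
  expect_equal(arrayTime(de), rep(c(1, 2, 4, 8, 12), 2))
  Y <- SummarizedExperiment::assay(de, "exprs")
  light <- arrayPhase(de) == "light"
  gB <- which(geneGroups(t1) == "B")[1]
  # group-B mean at lights-on exceeds its lights-off mean by ~ amplitude
  expect_equal(mean(Y[gB, light]) - mean(Y[gB, !light]), 2,
               tolerance = 0.05)
  gA <- which(geneGroups(t1) == "A")[1]
  expect_equal(mean(Y[gA, !light]) - mean(Y[gA, light]), 2,
               tolerance = 0.05)
  gC <- which(geneGroups(t1) == "C")[1]
  firstLight <- which(light)[1]
  expect_equal(Y[gC, firstLight] - mean(Y[gC, -firstLight]), 2,
               tolerance = 0.1)
})

test_that("identity-precision noise is uncorrelated and the GGM is consistent", {
  t0 <- makeSparseGGM(10, 0, 0.3, seed = 4, groups = "flat")
  de <- simulateDiurnalMatrix(t0, amplitude = 0, seed = 4)
  r <- correlationMatrix(de)
  expect_lt(median(abs(r[upper.tri(r)])), 0.4)      # n = 10 sampling noise
  t1 <- makeSparseGGM(10, 0.2, 0.35, seed = 5)
  big <- simulateDiurnalMatrix(t1, amplitude = 0, nReplicates = 500,
                               seed = 5)
  pc <- partialCorFromCorrelation(correlationMatrix(big))
  expect_lt(max(abs(pc - truePcor(t1))), 0.05)      # large-sample consistency
})

test_that("simulation at the study scale (p = 133, n = 10) runs end to end", {
  truth <- makeSparseGGM(133, 0.03, 0.35, seed = 6)
  de <- simulateDiurnalMatrix(truth, seed = 6)
  expect_equal(dim(de), c(133L, 10L))
  sh <- shrinkCorrelation(de)
  expect_gt(sh$lambda, 0)
  pc <- partialCorFromCorrelation(sh$r)             # invertible despite p >> n
  expect_true(all(is.finite(pc)))
  net <- edgeSignificance(pc, lambda = sh$lambda)
  expect_s4_class(net, "GGMNetwork")
})

test_that("compendium planting, truncation and purity hold", {
  comp0 <- makeCompendium(data.frame(regulator_gene = "R", target_gene = "T"),
                          nDecoys = 0, seed = 7)
  expect_equal(nrow(comp0), 1L)
  set.seed(30)
  wins <- vapply(1:40, function(s) {
    comp <- makeCompendium(data.frame(regulator_gene = "R", target_gene = "T"),
                           nDecoys = 40, effect = 0.5, noiseSd = 0.1,
                           seed = s)
    pl <- comp$correlation[comp$regulator_gene == "R"]
    pl > max(comp$correlation[comp$regulator_gene != "R"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
  compT <- makeCompendium(data.frame(regulator_gene = "R", target_gene = "T"),
                          nDecoys = 200, effect = 0.9, noiseSd = 0.8,
                          seed = 8)
  expect_true(all(abs(compT$correlation) <= 1))
  expect_identical(makeCompendium(data.frame(regulator_gene = "R",
                                             target_gene = "T"), seed = 9),
                   makeCompendium(data.frame(regulator_gene = "R",
                                             target_gene = "T"), seed = 9))
})

test_that("morphology generator produces circles exactly and plants effects", {
  circles <- makeMorphology(nObjects = 50,
                            lines = list(WT = list(axisRatio = 1,
                                                   ratioSd = 0)),
                            seed = 10)
  circ <- circularity(circles$area, circles$perimeter)
  expect_true(all(abs(circ - 1) < 1e-6))
  expect_identical(makeMorphology(nObjects = 20, seed = 11),
                   makeMorphology(nObjects = 20, seed = 11))
  # identical generating parameters: rejection near the nominal level
  set.seed(31)
  rej <- vapply(1:40, function(s) {
    wt <- starchnet:::morphLineDefaults$WT
    tab <- makeMorphology(nObjects = 60, lines = list(a = wt, b = wt),
                          seed = 100 + s)
    a <- tab$area[tab$line_label == "a" & tab$object_class == "chloroplast"]
    b <- tab$area[tab$line_label == "b" & tab$object_class == "chloroplast"]
    mannWhitneyU(a, b)$p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.15)
})

test_that("planted 30% area reduction is detected in most seeds", {
  set.seed(32)
  hits <- vapply(1:20, function(s) {
    tab <- makeMorphology(nObjects = 200, seed = 200 + s)
    a <- tab$area[tab$line_label == "mutant" &
                    tab$object_class == "chloroplast"]
    b <- tab$area[tab$line_label == "WT" & tab$object_class == "chloroplast"]
    mannWhitneyU(a, b)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
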