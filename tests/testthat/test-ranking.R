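test_that("regulator ranking sorts descending with competition ranks", {
  comp <- data.frame(regulator_gene = c("R1", "R2", "R3"),
                     target_gene = "T",
                     correlation = c(0.9, 0.1, -0.5),
                     family = c("F1", "F1", "F2"))
  rk <- rankRegulators(comp, "T")
  expect_equal(rk$regulator_gene, c("R1", "R2", "R3"))
  expect_equal(rk$rank_all_regulators, c(1L, 2L, 3L))
  expect_equal(rk$rank_in_family, c(1L, 2L, 1L))
  expect_lte(max(rk$rank_in_family), max(rk$rank_all_regulators))
  expect_error(rankRegulators(comp, "ZZZ"), "absent")
  # ties share the smaller rank; the next rank is skipped
  comp2 <- data.frame(regulator_gene = c("A", "B", "C"), target_gene = "T",
                      correlation = c(0.5, 0.5, 0.2), family = "F1")
  rk2 <- rankRegulators(comp2, "T")
  expect_equal(rk2$rank_all_regulators, c(1L, 1L, 3L))
})

test_that("a planted strong regulator ranks first among decoys", {
  set.seed(14)
  for (s in 1:20) {
    comp <- makeCompendium(data.frame(regulator_gene = "RP",
                                      target_gene = "T"),
                           nDecoys = 50, effect = 0.5, noiseSd = 0.15 / 2.5,
                           seed = s)
    # margin ~0.3 over the decoy maximum at this noise level
    rk <- rankRegulators(comp, "T")
    expect_equal(rk$regulator_gene[1], "RP")
  }
})

test_that("the population cutoff behaves at the mean and far tail", {
  set.seed(15)
  pop <- rnorm(100)
  expect_false(ttestCutoff(pop, mean(pop), confidence = 0.975))
  expect_true(ttestCutoff(pop, mean(pop) + 10 * sd(pop), confidence = 0.975))
  expect_error(ttestCutoff(rep(0.2, 10), 0.5), "zero-variance")
  expect_error(ttestCutoff(c(0.1, 0.2), 0.5), "at least 3")
})

test_that("cutoff pass-rate calibrates near 1 - confidence on normal data", {
  set.seed(16)
  hits <- 0; trials <- 0
  for (i in 1:400) {
    pop <- rnorm(40)
    cand <- rnorm(1)
    hits <- hits + ttestCutoff(pop, cand, confidence = 0.975)
    trials <- trials + 1
  }
  expect_gt(hits / trials, 0.01)
  expect_lt(hits / trials, 0.05)
})

test_that("precedence filter passes leaders and rejects laggards", {
  tm <- rep(c(1, 2, 4, 8, 12), 2)
  ph <- rep(c("dark", "light"), each = 5)
  h <- cycleHour(tm, ph)
  targ <- sin(2 * pi * h / 24)
  expect_true(precedenceFilter(targ, targ, tm, ph))
  lateReg <- sin(2 * pi * (h - 4) / 24)       # peaks 4 h after the target
  expect_false(precedenceFilter(lateReg, targ, tm, ph))
  earlyReg <- sin(2 * pi * (h + 4) / 24)      # peaks 4 h before the target
  expect_true(precedenceFilter(earlyReg, targ, tm, ph))
  expect_warning(ok <- precedenceFilter(rep(1, 10), targ, tm, ph), "flat")
  expect_true(ok)
  # recovered lags have the right sign and size
  expect_equal(attr(precedenceFilter(earlyReg, targ, tm, ph), "lag"), 4)
  expect_equal(attr(precedenceFilter(lateReg, targ, tm, ph), "lag"), -4)
})

test_that("binding-support join annotates Y/N/NA without spurious hits", {
  bind <- expand.grid(family = c("F1", "F2", "F3"),
                      target_gene = c("T1", "T2"),
                      stringsAsFactors = FALSE)
  bind$present <- c("Y", "N", "Y", "N", "Y", "N")
  rep6 <- data.frame(family = c("F1", "F2", "F3", "F1", "F9", "F3"),
                     target_gene = c("T1", "T1", "T1", "T2", "T2", "T9"))
  out <- annotateBindingSupport(rep6, bind)
  expect_equal(out$binding_support, c("Y", "N", "Y", "N", NA, NA))
})

test_that("final candidate selection requires both filters, not binding", {
  rep3 <- data.frame(target_gene = "T", regulator_gene = c("a", "b", "c"),
                     passes_ttest = c(FALSE, TRUE, TRUE),
                     passes_precedence = c(TRUE, FALSE, TRUE),
                     binding_support = c("Y", "Y", NA))
  out <- selectFinalCandidates(rep3)
  expect_equal(out$regulator_gene, "c")
  # filters commute: subsetting by either first gives the same final set
  byT <- rep3[rep3$passes_ttest, ]
  byP <- rep3[!is.na(rep3$passes_precedence) & rep3$passes_precedence, ]
  expect_equal(selectFinalCandidates(byT)$regulator_gene,
               selectFinalCandidates(byP)$regulator_gene)
})

test_that("candidateReport integrates ranking, cutoff and precedence", {
  set.seed(17)
  truth <- makeSparseGGM(6, 0.2, 0.3, seed = 17,
                         groups = c("B", "B", "A", "C", "D", "flat"))
  de <- simulateDiurnalMatrix(truth, amplitude = 2, noiseSd = 0.2, seed = 17)
  ids <- rownames(de)
  comp <- makeCompendium(data.frame(regulator_gene = ids[2],
                                    target_gene = ids[1]),
                         nDecoys = 30, effect = 0.6, noiseSd = 0.1,
                         seed = 18)
  pairs <- data.frame(regulator_gene = ids[2], target_gene = ids[1])
  bind <- data.frame(family = "F1", target_gene = ids[1], present = "Y")
  out <- candidateReport(pairs, comp, x = de, bindingTable = bind)
  expect_equal(nrow(out), 1L)
  expect_true(out$passes_ttest)                 # effect 0.6 over sd-0.1 decoys
  expect_equal(out$rank_in_family, 1L)
  expect_true(out$passes_precedence)            # same planted B shape
  expect_equal(out$binding_support, "Y")
  expect_equal(nrow(selectFinalCandidates(out)), 1L)
})
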