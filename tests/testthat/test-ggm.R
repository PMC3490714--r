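test_that("correlation matrix matches a direct covariance/sd computation", {
  set.seed(3)
  Y <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("g", 1:5), NULL))
  r <- correlationMatrix(Y)
  for (i in 1:5) for (j in 1:5) {
    num <- mean((Y[i, ] - mean(Y[i, ])) * (Y[j, ] - mean(Y[j, ])))
    oracle <- num / (sd(Y[i, ]) * sd(Y[j, ])) * 10 / 9
    expect_equal(r[i, j], oracle, tolerance = 1e-12)
  }
  expect_identical(r, t(r))
  Y2 <- rbind(Y, dup = Y[1, ], neg = -Y[1, ])
  r2 <- correlationMatrix(Y2)
  expect_equal(r2["g1", "dup"], 1)
  expect_equal(r2["g1", "neg"], -1)
  Y3 <- rbind(Y, const = rep(1, 10))
  expect_error(correlationMatrix(Y3), "zero-variance")
  expect_warning(r3 <- correlationMatrix(Y3, dropConstant = TRUE), "dropping")
  expect_equal(nrow(r3), 5L)
})

test_that("three-variable partial correlation follows its closed form", {
  expect_equal(partialCorr3(0.6, 0, 0), 0.6)          # no conditioning effect
  expect_equal(partialCorr3(0.6, 0.5, 0.5), 0.35 / 0.75)
  expect_equal(partialCorr3(0.4 * 0.3, 0.4, 0.3), 0)  # conditional independence
  expect_error(partialCorr3(0.5, 1, 0.3), "degenerate")
})

test_that("matrix-inverse partials agree with the three-variable formula", {
  set.seed(10)
  worst <- 0
  for (i in 1:300) {
    r <- randomCorr(3)
    pc <- partialCorFromCorrelation(r)
    worst <- max(worst,
                 abs(pc[1, 2] - partialCorr3(r[1, 2], r[1, 3], r[2, 3])),
                 abs(pc[1, 3] - partialCorr3(r[1, 3], r[1, 2], r[3, 2])),
                 abs(pc[2, 3] - partialCorr3(r[2, 3], r[2, 1], r[3, 1])))
  }
  expect_lt(worst, 1e-10)
})

test_that("partial correlations vanish off the dependence structure", {
  expect_equal(partialCorFromCorrelation(diag(4)), matrix(0, 4, 4),
               ignore_attr = TRUE)
  # block-diagonal correlation: no cross-block partials
  set.seed(5)
  bd <- as.matrix(Matrix::bdiag(randomCorr(3), randomCorr(2)))
  pc <- partialCorFromCorrelation(bd)
  expect_lt(max(abs(pc[1:3, 4:5])), 1e-12)
  # p = 2: the partial correlation is the marginal correlation
  r2 <- matrix(c(1, 0.37, 0.37, 1), 2)
  expect_equal(partialCorFromCorrelation(r2)[1, 2], 0.37)
})

test_that("shrinkage intensity adapts to the sampling regime", {
  set.seed(6)
  tBig <- makeSparseGGM(5, 0.5, 0.3, seed = 6)       # correlated 5-gene system
  big <- simulateDiurnalMatrix(tBig, amplitude = 0, nReplicates = 100,
                               seed = 6)
  shBig <- shrinkCorrelation(big)
  expect_lte(shBig$lambda, 0.1)
  truth <- makeSparseGGM(40, 0.1, 0.3, seed = 2)
  de <- simulateDiurnalMatrix(truth, amplitude = 0, seed = 2)   # p >> n
  sh <- shrinkCorrelation(de)
  expect_gt(sh$lambda, 0)
  expect_lt(kappa(sh$r), 1e6)                 # invertible, finite condition
  pc <- partialCorFromCorrelation(sh$r)
  expect_true(all(abs(pc) <= 1))
  # lambda = 1 target: all partial correlations vanish
  pcId <- partialCorFromCorrelation(diag(40))
  expect_equal(max(abs(pcId)), 0)
})

test_that("partial correlations are invariant to per-gene affine rescaling", {
  truth <- makeSparseGGM(10, 0.2, 0.3, seed = 9)
  de <- simulateDiurnalMatrix(truth, amplitude = 0, nReplicates = 3, seed = 9)
  Y <- SummarizedExperiment::assay(de, "exprs")
  sc <- runif(10, 0.5, 4)
  Y2 <- Y * sc + rnorm(10)
  pc1 <- partialCorFromCorrelation(shrinkCorrelation(Y)$r)
  pc2 <- partialCorFromCorrelation(shrinkCorrelation(Y2)$r)
  expect_equal(pc1, pc2, tolerance = 1e-9)
})

test_that("null partial-correlation density is correctly normalised", {
  expect_equal(nullPcorDensity(c(-0.5, 0, 0.77), 3), rep(0.5, 3))
  for (k in c(5, 20, 200)) {
    expect_equal(integrate(nullPcorDensity, -1, 1, kappa = k)$value, 1,
                 tolerance = 1e-6)
  }
  # closed-form tail used for p-values matches numeric integration
  pNum <- 2 * integrate(nullPcorDensity, 0.3, 1, kappa = 25)$value
  expect_equal(starchnet:::nullPcorPvalue(0.3, 25), pNum, tolerance = 1e-6)
})

test_that("mixture fit recovers pure-null and mixed parameters", {
  set.seed(12)
  x <- starchnet:::rNullPcor(4000, 20)
  fit <- fitNullMixture(x)
  expect_gte(eta0(fit), 0.9)
  expect_lt(abs(kappaNull(fit) - 20) / 20, 0.3)
  # 90/10 mixture with a wide alternative
  xa <- runif(400, -1, 1)
  fit2 <- fitNullMixture(c(starchnet:::rNullPcor(3600, 20), xa))
  expect_lt(abs(eta0(fit2) - 0.9), 0.1)
  expect_error(fitNullMixture(rep(0.1, 5)), "at least 10")
  expect_error(fitNullMixture(c(rep(0.2, 10), 1)), "inside")
})

test_that("edge significance is monotone in |pcor| and respects thresholds", {
  fit <- new("MixtureFit", eta0 = 0.9, kappa = 30, logLik = 0, n = 100L)
  expect_equal(starchnet:::nullPcorPvalue(0, 30), 1)
  ps <- starchnet:::nullPcorPvalue(c(0.1, 0.3, 0.6, 0.95), 30)
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[4], 1e-10)
  truth <- makeSparseGGM(15, 0.15, 0.35, seed = 31)
  de <- simulateDiurnalMatrix(truth, amplitude = 0, nReplicates = 20,
                              seed = 31)
  net <- ggmNetwork(de)
  ed <- edges(net)
  expect_gt(nrow(ed), 0)
  expect_true(all(ed$q_value <= net@qThreshold))
  expect_true(all(ed$gene_a < ed$gene_b))           # canonical ordering
  expect_identical(ed$sign, ifelse(ed$pcor >= 0, 1L, -1L))
  expect_true(validObject(net))
})
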