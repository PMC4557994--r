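test_that("OLS group statistics match the pooled two-sample t closed form", {
  # group0 {1,2,3}, group1 {4,5,6}: t = 3/sqrt(2/3), df = 4
  X <- matrix(c(1, 2, 3, 4, 5, 6), 1)
  co <- makeCohort(X, group = c(0, 0, 0, 1, 1, 1))
  st <- edgeTable(edgeRegression(co))
  expect_equal(st$beta, 3)
  expect_equal(st$t, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(st$df, 4)
  expect_equal(st$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(st$p, 0.02131, tolerance = 1e-3)
  expect_equal(st$mean0, 2)
  expect_equal(st$mean1, 5)
  expect_equal(st$n_used, 6L)
})

test_that("identical groups give t = 0, p = 1", {
  X <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 3), 3) + 0:2
  co <- makeCohort(X, group = c(0, 0, 0, 1, 1, 1))
  st <- edgeTable(edgeRegression(co))
  expect_equal(st$t, c(0, 0, 0))
  expect_equal(st$p, c(1, 1, 1))
})

test_that("a covariate collinear with group masks results with a warning", {
  set.seed(41)
  X <- matrix(rnorm(18), 3)
  co <- makeCohort(X, group = c(0, 0, 0, 1, 1, 1),
                   covariates = data.frame(dup = c(0, 0, 0, 1, 1, 1)))
  expect_warning(st <- edgeRegression(co, "dup"), "rank-deficient")
  expect_true(all(is.na(edgeTable(st)$t)))
  expect_error(edgeRegression(co, "nope"), "unknown covariate")
})

test_that("regression adjusts for a real covariate", {
  set.seed(42)
  n <- 40
  group <- rep(c(0, 1), each = n / 2)
  age <- rnorm(n) + 1.5 * group           # confounded covariate
  X <- matrix(2 * age + rnorm(n, sd = 0.2), 1)  # edge driven by age only
  co <- makeCohort(X, group, covariates = data.frame(age = age))
  pRaw <- edgeTable(edgeRegression(co))$p
  pAdj <- edgeTable(edgeRegression(co, "age"))$p
  expect_lt(pRaw, 0.01)   # spurious group effect without adjustment
  expect_gt(pAdj, 0.05)   # gone once age is in the model
})

test_that("missing-value policies behave as documented", {
  X <- matrix(c(1, NA, 3, 4, 5, 6), 1)
  co <- makeCohort(X, group = c(0, 0, 0, 1, 1, 1))
  # impute_group_mean: NA in group0 becomes mean(1, 3) = 2
  imp <- handleMissing(co, "impute_group_mean")
  expect_equal(edgeWeights(imp)[1, ], c(1, 2, 3, 4, 5, 6),
               ignore_attr = TRUE)
  # exclude: n_used drops by the number of missing subjects
  st <- edgeTable(edgeRegression(co))
  expect_equal(st$n_used, 5L)
  expect_equal(st$mean0, 2)
  # identity when nothing is missing
  full <- makeCohort(matrix(1:6, 1), group = c(0, 0, 0, 1, 1, 1))
  expect_identical(edgeWeights(handleMissing(full, "impute_group_mean")),
                   edgeWeights(full))
  # whole group missing stays masked under impute
  X2 <- matrix(c(NA, NA, NA, 4, 5, 6), 1)
  co2 <- makeCohort(X2, group = c(0, 0, 0, 1, 1, 1))
  expect_true(all(is.na(edgeWeights(handleMissing(co2, "impute_group_mean"))[1, 1:3])))
})

test_that("group mean networks average non-missing values per group", {
  atl <- tinyAtlas(3, c("A", "B", "C"))
  X <- rbind(c(1, 3, 2, 4), c(NA, 5, 1, 3), c(2, 2, 8, 8))
  co <- makeCohort(X, group = c(0, 0, 1, 1), atlas = atl, kind = "DMC")
  gm <- groupMeanNetworks(co)
  w0 <- netWeights(gm$group0); w1 <- netWeights(gm$group1)
  expect_equal(w0[1, 2], 2)   # mean(1, 3)
  expect_equal(w0[1, 3], 5)   # one exclusion -> mean over the rest
  expect_equal(w1[1, 2], 3)
  expect_equal(w1[2, 3], 8)
})

test_that("the Li & Ji rule reproduces its unit oracles", {
  expect_identical(mEffFromEigenvalues(c(3, 0, 0)), 1)
  expect_identical(mEffFromEigenvalues(rep(1, 7)), 7)
  expect_identical(mEffFromEigenvalues(c(1.5, 0.5)), 2)
})

test_that("M_eff detects duplicated and correlated edges and respects bounds", {
  set.seed(43)
  x <- rnorm(30)
  expect_equal(effectiveNumberOfTests(rbind(x, x)), 1)

  # shared latent factor -> M_eff well below M_G
  cfgL <- simulationConfig(seed = 44, latentLoading = 3)
  cfg0 <- simulationConfig(seed = 44)
  mL <- effectiveNumberOfTests(simulateEdgeCohort(cfgL)$cohort)
  m0 <- effectiveNumberOfTests(simulateEdgeCohort(cfg0)$cohort)
  expect_lt(mL, m0)
  expect_lt(mL, 435)
  # rank bound: at most n - 1 non-zero eigenvalues, each contributing < 2
  n <- ncol(edgeWeights(simulateEdgeCohort(cfg0)$cohort))
  expect_lte(m0, min(435, 2 * (n - 1)))

  expect_error(effectiveNumberOfTests(matrix(1, 3, 5)), "constant")
  expect_error(effectiveNumberOfTests(matrix(rnorm(4), 2, 2)), "3 subjects")
})

test_that("Gram-form and direct eigenvalues agree when both are feasible", {
  set.seed(45)
  X <- matrix(rnorm(20 * 50), 20, 50)  # M = 20 < n = 50: direct M x M route
  direct <- effectiveNumberOfTests(X)
  # force the Gram route by transposing roles: same standardized rows, M > n
  Z <- (X - rowMeans(X)) / sqrt(rowSums((X - rowMeans(X))^2) / 49)
  lamGram <- eigen(crossprod(Z) / 49, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(direct, mEffFromEigenvalues(lamGram), tolerance = 1e-8)
})

test_that("adjusted thresholds follow the Bonferroni/M_eff rule", {
  sp <- correctionSpec(mG = 435L, mEff = 1)
  expect_equal(sp@alphaAdj, 0.05)
  expect_equal(sp@s, 1)
  sp100 <- correctionSpec(mG = 435L, mEff = 100)
  expect_equal(sp100@alphaAdj, 5e-4)
  expect_equal(sp100@s, log10(0.05) / log10(5e-4), tolerance = 1e-12)
  expect_equal(sp100@s, 0.3941, tolerance = 1e-4)
  # monotone in mEff; worm reference identity holds exactly
  ms <- c(1, 2, 10, 50, 400)
  aa <- vapply(ms, function(m) correctionSpec(mG = 435L, mEff = m)@alphaAdj, 0)
  expect_true(all(diff(aa) < 0))
  for (m in ms) {
    spm <- correctionSpec(mG = 435L, mEff = m)
    expect_equal(-log10(spm@alphaAdj) * spm@s, -log10(0.05), tolerance = 1e-12)
  }
  expect_error(correctionSpec(mG = 10L, mEff = 100), "exceed")
  expect_error(correctionSpec(mG = 10L, mEff = 2, alpha = 1.2), "alpha")
})

test_that("cluster shift tests match the one-sample t closed form", {
  st <- makeEdgeStats(t = c(2, 1, 3, 2), p = rep(0.05, 4))
  sh <- clusterShiftTests(st)
  expect_equal(sh$mean_t, 2)
  expect_equal(sh$t, 4.899, tolerance = 1e-3)
  expect_equal(sh$df, 3)
  expect_equal(sh$p, 0.016277, tolerance = 1e-4)

  # symmetric about zero -> t = 0, p = 1
  sh0 <- clusterShiftTests(makeEdgeStats(t = c(-1, 1), p = c(0.3, 0.3)))
  expect_equal(sh0$t, 0)
  expect_equal(sh0$p, 1)

  # constant t -> zero variance -> masked with warning
  expect_warning(shc <- clusterShiftTests(makeEdgeStats(t = c(2, 2, 2),
                                                        p = rep(0.1, 3))),
                 "zero variance|masked")
  expect_true(is.na(shc$p))
})

test_that("Welch-from-summary agrees with t.test on raw-data-equivalent input", {
  set.seed(46)
  a <- rnorm(15, 1, 2); b <- rnorm(12, 0, 1)
  ref <- t.test(a, b)
  got <- welchFromSummary(mean(a), sd(a), 15, mean(b), sd(b), 12)
  expect_equal(unname(got["t"]), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(unname(got["df"]), unname(ref$parameter), tolerance = 1e-12)
  expect_equal(unname(got["p"]), ref$p.value, tolerance = 1e-12)

  same <- welchFromSummary(5, 1, 10, 5, 1, 10)
  expect_equal(unname(same["t"]), 0)
  expect_equal(unname(same["p"]), 1)
  expect_error(welchFromSummary(1, 0, 10, 2, 1, 10), "positive")
  expect_error(welchFromSummary(1, 1, 1, 2, 1, 10), "at least 2")
})

test_that("2x2 chi-squared matches the hand-computed statistic and scales", {
  got <- chisq2x2(17, 6, 12, 9)
  expect_equal(unname(got["statistic"]), 1.374, tolerance = 1e-3)
  ref <- suppressWarnings(chisq.test(matrix(c(17, 6, 12, 9), 2, byrow = TRUE),
                                     correct = FALSE))
  expect_equal(unname(got["statistic"]), unname(ref$statistic), tolerance = 1e-12)

  ident <- chisq2x2(13, 24, 13, 24)
  expect_equal(unname(ident["statistic"]), 0)
  expect_equal(unname(ident["p"]), 1)

  dbl <- chisq2x2(34, 12, 24, 18)
  expect_equal(unname(dbl["statistic"]), 2 * unname(got["statistic"]),
               tolerance = 1e-12)

  withCorr <- chisq2x2(17, 6, 12, 9, correct = TRUE)
  expect_lt(unname(withCorr["statistic"]), unname(got["statistic"]))
  expect_error(chisq2x2(0, 0, 3, 4), "margins")
})
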