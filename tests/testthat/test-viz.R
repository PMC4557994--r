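test_that("worm y follows -log10(p) * sign(t) * s", {
  corr <- correctionSpec(mG = 435L, mEff = 100)
  st <- makeEdgeStats(t = c(2, -2, 0.5), p = c(0.01, 0.01, 1))
  wd <- wormPlotData(st, corr)
  wd <- wd[order(wd$edge), ]
  expect_equal(wd$y[1], 2 * corr@s, tolerance = 1e-12)
  expect_equal(wd$y[1], 0.7882, tolerance = 1e-3)
  expect_equal(wd$y[2], -2 * corr@s, tolerance = 1e-12)
  expect_equal(wd$y[3], 0)  # p = 1 -> 0 regardless of t sign
})

test_that("an edge at p = alpha_adj sits exactly on the reference line", {
  set.seed(51)
  for (k in 1:50) {
    alpha <- runif(1, 0.001, 0.2)
    mEff <- runif(1, 1, 5000)
    corr <- correctionSpec(mG = 10000L, mEff = mEff, alpha = alpha)
    st <- makeEdgeStats(t = c(1, -1), p = rep(corr@alphaAdj, 2))
    wd <- wormPlotData(st, corr)
    expect_lt(max(abs(abs(wd$y) - (-log10(alpha)))), 1e-12)
    expect_equal(attr(wd, "reference"), -log10(alpha))
  }
})

test_that("worm ordering is ascending in t with stable tie-break by edge", {
  st <- makeEdgeStats(t = c(0.5, -1, 0.5, 2), p = c(0.2, 0.1, 0.3, 0.01),
                      cluster = "Fro/Fro")
  wd <- wormPlotData(st, correctionSpec(mG = 4L, mEff = 2))
  expect_equal(wd$edge, c(2L, 1L, 3L, 4L))      # tie 1 vs 3 -> edge order
  expect_setequal(wd$within_index, 1:4)          # a permutation
  expect_true(all(diff(wd$x) > 0))
  # p = 0 underflow clips with a warning
  expect_warning(w0 <- wormPlotData(makeEdgeStats(1, 0),
                                    correctionSpec(mG = 4L, mEff = 2)),
                 "underflow")
  expect_true(is.finite(w0$y))
})

test_that("bimodal histograms conserve counts and encode group mix", {
  set.seed(52)
  cfg <- simulationConfig(seed = 52, nClusters = 2, regionsPerCluster = 3,
                          n0 = 6, n1 = 6)
  cohorts <- list(DMC = simulateEdgeCohort(cfg, kind = "DMC")$cohort,
                  fMT = simulateEdgeCohort(simulationConfig(seed = 53,
                    nClusters = 2, regionsPerCluster = 3,
                    n0 = 6, n1 = 6))$cohort)
  bm <- bimodalPlotData(cohorts, mode = "group_means", bins1d = 20, bins2d = 8)
  M <- nrow(cohorts$DMC)
  for (k in names(cohorts)) {
    expect_equal(sum(bm$marginal[[k]]$count0), M)
    expect_equal(sum(bm$marginal[[k]]$count1), M)
  }
  j <- bm$joint[["DMCxfMT"]]$bins
  expect_equal(sum(j$count0), M)
  expect_equal(sum(j$count1), M)
  # pure group-0 bin -> red; pure group-1 -> blue; balanced -> magenta
  pure0 <- j[j$count0 > 0 & j$count1 == 0, ]
  if (nrow(pure0)) expect_true(all(pure0$r == 1 & pure0$b == 0))
  pure1 <- j[j$count1 > 0 & j$count0 == 0, ]
  if (nrow(pure1)) expect_true(all(pure1$b == 1 & pure1$r == 0))
  even <- j[j$count0 == j$count1, ]
  if (nrow(even)) expect_true(all(even$r == 1 & even$b == 1))
  expect_true(all(j$alpha > 0 & j$alpha <= 1))
  expect_equal(max(j$alpha), 1)

  bt <- bimodalPlotData(cohorts, mode = "t_stats", bins1d = 20, bins2d = 8)
  expect_equal(sum(bt$marginal$DMC$count), M)
  expect_true(all(bt$joint[["DMCxfMT"]]$bins$g == 1))
  expect_error(bimodalPlotData(cohorts, bins1d = 1), "at least 2 bins")
})

test_that("connectogram draws exactly the significant edges with monotone opacity", {
  corr <- correctionSpec(mG = 435L, mEff = 10)  # alpha_adj = 0.005
  atl <- tinyAtlas(4, c("Fro", "Fro", "Temp", "Occ"))
  p <- c(0.005, 0.0049, 5e-5, 0.5, 0.2, 0.9)
  t <- c(1, 2, -3, 1, -1, 1)
  tab <- edgeTable(makeEdgeStats(t, p))
  index <- buildEdgeIndex(atl)
  tab$region_a <- regionIds(atl)[index@pairs[, 1]]
  tab$region_b <- regionIds(atl)[index@pairs[, 2]]
  tab$cluster_pair <- edgeClusterPairs(atl, index)
  st <- new("EdgeStats", table = tab, kind = "fMT")

  cg <- connectogramData(st, corr, atl)
  expect_equal(nrow(cg$edges), sum(p < corr@alphaAdj))  # strict threshold
  expect_equal(nrow(cg$edges), 2)
  expect_setequal(cg$edges$color, c("red", "blue"))
  # the smaller p is strictly more opaque; boundary-adjacent edge near 0.3
  ord <- order(cg$edges$p)
  expect_gt(cg$edges$opacity[ord[1]], cg$edges$opacity[ord[2]])
  expect_true(all(cg$edges$opacity >= 0.3 & cg$edges$opacity <= 1))
  # node layout: equal spacing, contiguous clusters, degree-driven saturation
  expect_equal(diff(cg$nodes$angle_deg), rep(90, 3))
  expect_equal(rle(cg$nodes$cluster)$values, c("Fro", "Temp", "Occ"))
  expect_equal(max(cg$nodes$saturation), 1)
  expect_true(all(cg$nodes$saturation[cg$nodes$degree == 0] == 0.25))
})

test_that("a run with no significant edges yields a valid empty connectogram", {
  corr <- correctionSpec(mG = 435L, mEff = 100)
  atl <- tinyAtlas(4)
  st <- makeEdgeStats(t = rnorm(6), p = runif(6, 0.5, 1))
  cg <- connectogramData(st, corr, atl)
  expect_equal(nrow(cg$edges), 0)
  expect_equal(nrow(cg$nodes), 4)
  expect_true(all(cg$nodes$saturation == 0.25))
})

test_that("matrix plot data is symmetric with a null diagonal and masked cells", {
  atl <- tinyAtlas(3, c("A", "B", "C"))
  w <- matrix(c(0, 1, NA, 1, 0, 3, NA, 3, 0), 3)
  net <- ConnectivityNetwork(w, "DMC", regionIds = regionIds(atl))
  m <- matrixPlotData(net)
  expect_true(all(is.na(diag(m))))
  expect_identical(m, t(m))
  expect_true(is.na(m[1, 3]))
  expect_equal(m[2, 3], 3)

  st <- makeEdgeStats(t = c(1, 2, 3), p = rep(0.1, 3))
  mt <- matrixPlotData(st, atlas = atl)
  expect_identical(mt, t(mt))
  expect_equal(mt[1, 2], 1)
})

test_that("plot wrappers return ggplot objects", {
  corr <- correctionSpec(mG = 6L, mEff = 3)
  atl <- tinyAtlas(4)
  st <- makeEdgeStats(t = rnorm(6), p = runif(6, 1e-4, 1))
  tab <- edgeTable(st)
  index <- buildEdgeIndex(atl)
  tab$region_a <- regionIds(atl)[index@pairs[, 1]]
  tab$region_b <- regionIds(atl)[index@pairs[, 2]]
  st <- new("EdgeStats", table = tab, kind = "fMT")
  expect_s3_class(plotWorm(wormPlotData(st, corr)), "ggplot")
  expect_s3_class(plotConnectogram(connectogramData(st, corr, atl)), "ggplot")
  expect_s3_class(plotMatrix(matrixPlotData(st, atlas = atl)), "ggplot")
})
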