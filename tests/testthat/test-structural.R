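twoRegionGrid <- function(labv, costv, fav = NULL, dims = c(length(labv), 1, 1),
                          voxelSize = c(1, 1, 1)) {
  if (is.null(fav)) fav <- rep(0.5, prod(dims))
  VoxelGrid(array(as.integer(labv), dims), array(fav, dims),
            cost = array(costv, dims), voxelSize = voxelSize)
}

test_that("hand-enumerable grids give the expected DMC", {
  atl <- twoRegionAtlas()
  # 3x1x1 grid [A, bg, B], unit cost: two unit steps at mean cost 1 -> 2
  g <- twoRegionGrid(c(1, 0, 2), c(1, 1, 1))
  res <- minCostPathNetwork(g, atl)
  expect_equal(netWeights(res$dmc)[1, 2], 2)
  # zero-cost field, adjacent regions -> DMC = 0
  g0 <- twoRegionGrid(c(1, 2), c(0, 0))
  expect_equal(netWeights(minCostPathNetwork(g0, atl)$dmc)[1, 2], 0)
  # step length scales with voxel size
  g2 <- twoRegionGrid(c(1, 0, 2), c(1, 1, 1), voxelSize = c(2, 1, 1))
  expect_equal(netWeights(minCostPathNetwork(g2, atl)$dmc)[1, 2], 4)
})

test_that("the search detours around an impassable column and matches brute force", {
  atl <- twoRegionAtlas()
  # 3x3x1: A at (1,2), B at (3,2), huge cost at the center column
  lab <- array(0L, c(3, 3, 1)); lab[1, 2, 1] <- 1L; lab[3, 2, 1] <- 2L
  costv <- array(1, c(3, 3, 1)); costv[2, 2, 1] <- 1e6
  g <- VoxelGrid(lab, array(0.5, c(3, 3, 1)), cost = costv)
  got <- netWeights(minCostPathNetwork(g, atl)$dmc)[1, 2]
  expect_equal(got, bruteForceDMC(g, 1, 2), tolerance = 1e-9)
  expect_lt(got, 1e5)  # it went around, not through
})

test_that("search equals the exhaustive oracle on random small grids", {
  atl <- twoRegionAtlas()
  set.seed(31)
  for (k in 1:25) {
    g <- randomGridInstance(sample(3:4, 1), sample(3:4, 1))
    got <- netWeights(minCostPathNetwork(g, atl, keepPaths = FALSE)$dmc)[1, 2]
    expect_equal(got, bruteForceDMC(g, 1, 2), tolerance = 1e-9)
  }
})

test_that("DMC is monotone in voxel cost, non-negative and symmetric", {
  atl <- twoRegionAtlas()
  set.seed(32)
  for (k in 1:10) {
    g <- randomGridInstance(4, 3)
    d0 <- netWeights(minCostPathNetwork(g, atl, keepPaths = FALSE)$dmc)
    expect_true(all(d0[upper.tri(d0)] >= 0, na.rm = TRUE))
    expect_equal(d0, t(d0))
    up <- g@cost
    v <- sample(length(up), 1)
    up[v] <- up[v] + runif(1, 0.5, 2)
    g2 <- VoxelGrid(g@labels, g@fa, cost = up, voxelSize = g@voxelSize)
    d1 <- netWeights(minCostPathNetwork(g2, atl, keepPaths = FALSE)$dmc)
    expect_true(all(d1[upper.tri(d1)] >= d0[upper.tri(d0)] - 1e-12, na.rm = TRUE))
  }
})

test_that("a connected grid yields a fully connected network; empty regions are masked", {
  sc <- simulateStructuralScene(simulationConfig(seed = 33, n0 = 2, n1 = 2,
                                                 nClusters = 2,
                                                 regionsPerCluster = 3))
  nets <- minCostPathNetwork(sc$grids[[1]], sc$atlas, keepPaths = FALSE)
  w <- netWeights(nets$dmc)
  expect_true(all(is.finite(w[upper.tri(w)])))

  # drop one region's voxels: its edges must be masked, with a warning
  g <- sc$grids[[1]]
  lab <- g@labels; lab[lab == 2L] <- 0L
  g2 <- VoxelGrid(lab, g@fa, cost = g@cost, voxelSize = g@voxelSize)
  expect_warning(nets2 <- minCostPathNetwork(g2, sc$atlas, keepPaths = FALSE),
                 "without voxels")
  w2 <- netWeights(nets2$dmc)
  expect_true(all(is.na(w2[2, -2])))
  others <- w2[-2, -2]
  expect_true(all(is.finite(others[upper.tri(others)])))
})

test_that("path records are consistent and DFA follows its definition", {
  atl <- twoRegionAtlas()
  g <- twoRegionGrid(c(1, 0, 2), c(1, 1, 1), fav = c(0.5, 0.6, 0.7))
  res <- minCostPathNetwork(g, atl)
  p <- res$paths[["1-2"]]
  expect_equal(nrow(p$voxels), 3)
  expect_equal(p$faSum, 1.8)
  expect_equal(p$euclideanMm, 2)
  expect_equal(netWeights(res$dfa)[1, 2], 0.9)
  expect_equal(dfaOfPath(p, g), 0.9)
  # linearity in FA
  g2 <- VoxelGrid(g@labels, array(c(1, 1, 1), c(3, 1, 1)), cost = g@cost)
  expect_equal(dfaOfPath(p, g2), 1.5)  # FA == 1 everywhere -> 3/2
  gz <- VoxelGrid(g@labels, array(0, c(3, 1, 1)), cost = g@cost)
  expect_equal(dfaOfPath(p, gz), 0)
  expect_error(dfaOfPath(list(voxels = p$voxels[1, , drop = FALSE]), g),
               "two voxels")
})

test_that("arc-length DFA uses the path arc, not the endpoint chord", {
  atl <- twoRegionAtlas()
  # L-shaped detour in a 3x3 slab
  lab <- array(0L, c(3, 3, 1)); lab[1, 1, 1] <- 1L; lab[3, 1, 1] <- 2L
  costv <- array(1, c(3, 3, 1)); costv[2, 1, 1] <- 1e6
  g <- VoxelGrid(lab, array(0.5, c(3, 3, 1)), cost = costv)
  resE <- minCostPathNetwork(g, atl, distance = "endpoint")
  resA <- minCostPathNetwork(g, atl, distance = "arc")
  expect_gt(netWeights(resE$dfa)[1, 2], netWeights(resA$dfa)[1, 2])
})

test_that("directed symmetrization takes the minimum cost and its companion", {
  co <- matrix(c(0, 2, 3.5, 0), 2, byrow = TRUE)
  fa <- matrix(c(0, 0.4, 0.6, 0), 2, byrow = TRUE)
  sy <- symmetrizeDirected(co, fa)
  expect_equal(netWeights(sy$dmc)[1, 2], 2)
  expect_equal(netWeights(sy$dfa)[1, 2], 0.4)

  # already-symmetric input is unchanged
  cs <- matrix(c(0, 1.5, 1.5, 0), 2)
  fs <- matrix(c(0, 0.3, 0.3, 0), 2)
  sy2 <- symmetrizeDirected(cs, fs)
  expect_equal(netWeights(sy2$dmc), cs, ignore_attr = TRUE)
  expect_equal(netWeights(sy2$dfa), fs, ignore_attr = TRUE)

  # tie -> i < j direction
  cot <- matrix(c(0, 2, 2, 0), 2)
  fat <- matrix(c(0, 0.4, 0.6, 0), 2, byrow = TRUE)
  expect_equal(netWeights(symmetrizeDirected(cot, fat)$dfa)[1, 2], 0.4)

  expect_error(symmetrizeDirected(co, fa[1, , drop = FALSE]), "same size")
})
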