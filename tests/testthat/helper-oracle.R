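# Independent exhaustive-enumeration oracle for the minimum-cost path:
# depth-first search over all simple voxel paths from any source-region
# voxel to the first-reached target-region voxel, with the same transition
# cost (step length in mm x mean of the two voxel costs). Exact on small
# grids; branch-and-bound pruning (abandon a prefix once its cost reaches
# the best complete path) discards only provably suboptimal paths.
bruteForceDMC <- function(grid, srcLabel, dstLabel, connectivity = 26L) {
  dims <- dim(grid@labels)
  n <- prod(dims)
  coords <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                                  k = seq_len(dims[3])))
  costv <- as.vector(grid@cost)
  labv <- as.vector(grid@labels)
  vs <- grid@voxelSize
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  nbr <- vector("list", n); stepw <- vector("list", n)
  for (v in seq_len(n)) {
    cv <- coords[v, ]
    for (o in seq_len(nrow(offs))) {
      cu <- cv + offs[o, ]
      if (any(cu < 1L) || any(cu > dims)) next
      u <- (cu[3] - 1L) * dims[1] * dims[2] + (cu[2] - 1L) * dims[1] + cu[1]
      nbr[[v]] <- c(nbr[[v]], u)
      stepw[[v]] <- c(stepw[[v]], sqrt(sum((offs[o, ] * vs)^2)))
    }
  }
  src <- which(labv == srcLabel)
  if (!length(src) || !any(labv == dstLabel)) return(NA_real_)
  best <- Inf
  visited <- logical(n)
  dfs <- function(v, acc) {
    if (acc >= best) return(invisible())
    if (labv[v] == dstLabel) { best <<- acc; return(invisible()) }
    visited[v] <<- TRUE
    nb <- nbr[[v]]; sw <- stepw[[v]]
    for (k in seq_along(nb)) {
      u <- nb[k]
      if (!visited[u])
        dfs(u, acc + sw[k] * (costv[v] + costv[u]) / 2)
    }
    visited[v] <<- FALSE
  }
  for (s in src) dfs(s, 0)
  best
}

# Random two-region grid instance on a <= nx x ny x 1 slab.
randomGridInstance <- function(nx = 4L, ny = 4L) {
  dims <- c(nx, ny, 1L)
  n <- prod(dims)
  labv <- integer(n)
  picks <- sample.int(n, 2L)
  labv[picks[1]] <- 1L
  labv[picks[2]] <- 2L
  VoxelGrid(array(labv, dims),
            fa = array(runif(n), dims),
            cost = array(runif(n, 0.05, 2), dims),
            voxelSize = c(1, 1, 1))
}
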