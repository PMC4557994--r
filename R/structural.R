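#' Construct a voxel grid
#'
#' @param labels 3D integer array; 0 = background, k > 0 = atlas region k.
#' @param fa 3D array of fractional anisotropy in [0, 1], same shape.
#' @param cost 3D non-negative local cost array, same shape. Defaults to
#'   [defaultCostFromFA()] applied to `fa`: any cost model can be plugged
#'   in here.
#' @param voxelSize numeric(3) voxel edge lengths in mm.
#' @return a [VoxelGrid-class].
#' @export
VoxelGrid <- function(labels, fa, cost = defaultCostFromFA(fa),
                      voxelSize = c(1, 1, 1)) {
  labels <- array(as.integer(labels), dim = dim(labels))
  new("VoxelGrid", cost = cost, fa = fa, labels = labels,
      voxelSize = as.numeric(voxelSize))
}

#' Default local cost from fractional anisotropy
#'
#' c(v) = 1 - FA(v), clipped to [eps, 1]: traversal is cheap along
#' coherent high-FA white matter and expensive elsewhere. This is a simple
#' stand-in cost model; any non-negative cost image may be supplied to
#' [VoxelGrid()] instead.
#'
#' @param fa array of FA values in [0, 1].
#' @param eps lower clip (default 1e-3) keeping the cost strictly positive.
#' @return array of local costs.
#' @export
defaultCostFromFA <- function(fa, eps = 1e-3) {
  pmin(pmax(1 - fa, eps), 1)
}

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@labels)
  cat(sprintf("VoxelGrid %dx%dx%d, %d regions, voxel %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], max(object@labels),
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

# Neighborhood offsets: half-space representatives so each undirected edge
# appears once. 26-connectivity by default (reduces metrication error);
# 6-connectivity available.
.gridOffsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
    keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
    storage.mode(g) <- "integer"
    g[keep, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

# Undirected lattice edges (linear voxel indices) with physical step lengths.
# Topology depends only on dim/voxelSize/connectivity, so it is reusable
# across subjects sharing a grid.
.gridLattice <- function(dims, voxelSize, connectivity = 26L) {
  offs <- .gridOffsets(connectivity)
  ii <- seq_len(dims[1]); jj <- seq_len(dims[2]); kk <- seq_len(dims[3])
  coords <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  from <- integer(0); to <- integer(0); len <- numeric(0)
  for (o in seq_len(nrow(offs))) {
    d <- offs[o, ]
    ok <- coords[, 1] + d[1] >= 1L & coords[, 1] + d[1] <= dims[1] &
          coords[, 2] + d[2] >= 1L & coords[, 2] + d[2] <= dims[2] &
          coords[, 3] + d[3] >= 1L & coords[, 3] + d[3] <= dims[3]
    a <- coords[ok, , drop = FALSE]
    b <- sweep(a, 2L, d, `+`)
    lin <- function(m) (m[, 3] - 1L) * dims[1] * dims[2] +
                       (m[, 2] - 1L) * dims[1] + m[, 1]
    from <- c(from, lin(a)); to <- c(to, lin(b))
    len <- c(len, rep.int(sqrt(sum((d * voxelSize)^2)), nrow(a)))
  }
  list(from = from, to = to, len = len, coords = coords)
}

#' Minimum-cost-path structural networks (DMC and DFA)
#'
#' For every unordered region pair, runs a shortest-path search through the
#' voxel cost field. All voxels of the source region are seeded at cost 0
#' (travel within the source region is free) and the edge weight is the
#' minimum over target-region voxels of the cumulative path cost, where one
#' step u -> v costs (step length in mm) x (cost(u) + cost(v)) / 2. DMC is
#' that minimum cumulative cost; DFA is the sum of FA over the optimal
#' path's voxels divided by the straight-line distance between its
#' endpoints (or the path arc length, see `distance`). Costs are
#' undirected, so both matrices are symmetric by construction. Regions with
#' no voxels, and pairs with no finite path, have their edges masked.
#'
#' @param grid a [VoxelGrid-class].
#' @param atlas a [RegionAtlas-class]; region k of the atlas corresponds to
#'   label value k.
#' @param connectivity voxel neighborhood, 26 (default) or 6.
#' @param distance denominator of DFA: `"endpoint"` (straight-line
#'   endpoint-to-endpoint distance, default) or `"arc"` (path arc length).
#' @param subjectId subject identifier.
#' @param keepPaths if TRUE (default) return the optimal voxel paths.
#' @return list with elements `dmc` and `dfa`
#'   ([ConnectivityNetwork-class]) and `paths` (named list of path
#'   records; see [dfaOfPath()]).
#' @export
minCostPathNetwork <- function(grid, atlas, connectivity = 26L,
                               distance = c("endpoint", "arc"),
                               subjectId = "subject", keepPaths = TRUE) {
  distance <- match.arg(distance)
  r <- nRegions(atlas)
  dims <- dim(grid@labels)
  n <- prod(dims)
  lat <- .gridLattice(dims, grid@voxelSize, connectivity)
  costv <- as.vector(grid@cost)
  fav <- as.vector(grid@fa)
  wts <- lat$len * (costv[lat$from] + costv[lat$to]) / 2
  # vertex n+1 is a detachable super-source re-wired per region
  g <- igraph::make_empty_graph(n = n + 1L, directed = FALSE)
  g <- igraph::add_edges(g, rbind(lat$from, lat$to), weight = wts)
  labv <- as.vector(grid@labels)
  regionVox <- split(seq_len(n), factor(labv, levels = seq_len(r)))
  empty <- vapply(regionVox, length, 1L) == 0L
  if (any(empty))
    warning("region(s) without voxels: ",
            paste(regionIds(atlas)[empty], collapse = ", "),
            "; their edges are masked")
  phys <- sweep(lat$coords, 2L, grid@voxelSize, `*`)
  dmc <- matrix(NA_real_, r, r); diag(dmc) <- 0
  dfa <- matrix(NA_real_, r, r); diag(dfa) <- 0
  paths <- list()
  for (i in seq_len(r - 1L)) {
    src <- regionVox[[i]]
    if (!length(src)) next
    gi <- igraph::add_edges(g, rbind(n + 1L, src), weight = 0)
    dv <- suppressWarnings(
      igraph::distances(gi, v = n + 1L, weights = igraph::E(gi)$weight))[1L, ]
    targets <- integer(0); pairIdx <- integer(0)
    for (j in (i + 1L):r) {
      tv <- regionVox[[j]]
      if (!length(tv)) next
      dj <- dv[tv]
      if (!any(is.finite(dj))) next
      best <- tv[which(dj == min(dj))]
      targets <- c(targets, min(best))  # tie-break: smallest linear index
      pairIdx <- c(pairIdx, j)
      dmc[i, j] <- dmc[j, i] <- min(dj)
    }
    if (!length(targets)) next
    sp <- suppressWarnings(igraph::shortest_paths(
      gi, from = n + 1L, to = targets, weights = igraph::E(gi)$weight,
      output = "vpath"))$vpath
    for (k in seq_along(targets)) {
      j <- pairIdx[k]
      vp <- as.integer(sp[[k]])
      vp <- vp[vp != n + 1L]
      rec <- list(
        voxels = lat$coords[vp, , drop = FALSE],
        regions = c(i, j),
        cumulativeCost = dmc[i, j],
        faSum = sum(fav[vp]),
        euclideanMm = sqrt(sum((phys[vp[length(vp)], ] - phys[vp[1L], ])^2)),
        arcMm = if (length(vp) > 1L)
          sum(sqrt(rowSums((phys[vp[-1L], , drop = FALSE] -
                            phys[vp[-length(vp)], , drop = FALSE])^2))) else 0)
      den <- if (distance == "endpoint") rec$euclideanMm else rec$arcMm
      dfa[i, j] <- dfa[j, i] <- if (den > 0) rec$faSum / den else NA_real_
      if (keepPaths) paths[[paste0(i, "-", j)]] <- rec
    }
  }
  ids <- regionIds(atlas)
  list(
    dmc = ConnectivityNetwork(dmc, "DMC", subjectId, regionIds = ids),
    dfa = ConnectivityNetwork(dfa, "DFA", subjectId, regionIds = ids),
    paths = paths)
}

#' Path-FA measure of a stored path record
#'
#' Divides the sum of FA over the path's voxels (endpoints inclusive) by
#' the straight-line distance between its endpoints (or the arc length).
#'
#' @param path a path record from [minCostPathNetwork()] (list with a
#'   `voxels` coordinate matrix).
#' @param grid the [VoxelGrid-class] the path was traced in.
#' @param distance `"endpoint"` (default) or `"arc"`.
#' @return non-negative scalar.
#' @export
dfaOfPath <- function(path, grid, distance = c("endpoint", "arc")) {
  distance <- match.arg(distance)
  vox <- path$voxels
  if (is.null(dim(vox)) || nrow(vox) < 2L)
    stop("path must contain at least two voxels")
  phys <- sweep(vox, 2L, grid@voxelSize, `*`)
  den <- if (distance == "endpoint") {
    sqrt(sum((phys[nrow(phys), ] - phys[1L, ])^2))
  } else {
    sum(sqrt(rowSums((phys[-1L, , drop = FALSE] -
                      phys[-nrow(phys), , drop = FALSE])^2)))
  }
  if (den == 0) stop("degenerate path: coincident endpoints")
  sum(grid@fa[vox]) / den
}

#' Symmetrize directed minimum-cost networks
#'
#' Structural path search run separately in each direction yields two costs
#' per region pair; the symmetric network takes the minimum of the two, and
#' the companion DFA value from whichever direction attained it. Cost ties
#' resolve to the i -> j direction with i < j.
#'
#' @param cost r x r directed cost matrix (`cost[i, j]` = cost i -> j).
#' @param companion r x r directed companion (DFA) matrix.
#' @param subjectId subject identifier attached to the outputs.
#' @return list with `dmc` and `dfa` [ConnectivityNetwork-class] objects.
#' @examples
#' co <- matrix(c(0, 2, 3.5, 0), 2, byrow = TRUE)
#' fa <- matrix(c(0, 0.4, 0.6, 0), 2, byrow = TRUE)
#' netWeights(symmetrizeDirected(co, fa)$dfa)[1, 2]  # 0.4
#' @export
symmetrizeDirected <- function(cost, companion, subjectId = "subject") {
  cost <- as.matrix(cost); companion <- as.matrix(companion)
  if (!identical(dim(cost), dim(companion)) || nrow(cost) != ncol(cost))
    stop("cost and companion must be square matrices of the same size")
  tc <- t(cost)
  dmc <- pmin(cost, tc)
  # upper triangle decides: keep forward companion unless the reverse cost
  # is strictly smaller
  useRev <- tc < cost
  dfa <- ifelse(useRev, t(companion), companion)
  dfa[lower.tri(dfa)] <- t(dfa)[lower.tri(dfa)]
  diag(dmc) <- 0; diag(dfa) <- diag(companion)
  list(dmc = ConnectivityNetwork(dmc, "DMC", subjectId),
       dfa = ConnectivityNetwork(dfa, "DFA", subjectId))
}
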