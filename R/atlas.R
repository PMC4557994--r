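#' Construct a region atlas
#'
#' @param regions data.frame (or coercible) with columns `region_id`,
#'   `name`, `hemisphere` (`L`/`R`/`none`) and `cluster` (lobe label such
#'   as `Sub`, `Occ`, `Par`, `Temp`, `Fro`, `Cb`). Row order is preserved
#'   and defines matrix row/column order throughout.
#' @return a [RegionAtlas-class] object.
#' @examples
#' atl <- RegionAtlas(data.frame(
#'   region_id = c("lh.a", "rh.a"), name = c("A left", "A right"),
#'   hemisphere = c("L", "R"), cluster = c("Fro", "Fro")))
#' nRegions(atl)
#' @export
RegionAtlas <- function(regions) {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  for (cc in c("region_id", "name", "hemisphere", "cluster"))
    if (cc %in% names(regions)) regions[[cc]] <- as.character(regions[[cc]])
  rownames(regions) <- NULL
  new("RegionAtlas", regions = regions)
}

#' @rdname nRegions
#' @export
setMethod("nRegions", "RegionAtlas", function(x) nrow(x@regions))

#' @rdname regionIds
#' @export
setMethod("regionIds", "RegionAtlas", function(x) x@regions$region_id)

#' @rdname regionClusters
#' @export
setMethod("regionClusters", "RegionAtlas", function(x) x@regions$cluster)

setMethod("show", "RegionAtlas", function(object) {
  df <- object@regions
  cl <- table(df$cluster)
  cat("RegionAtlas with", nrow(df), "regions in", length(cl), "clusters\n")
  cat("  clusters:", paste(sprintf("%s(%d)", names(cl), cl), collapse = " "), "\n")
})

#' Build the edge index of an atlas
#'
#' Enumerates the M_G = r(r-1)/2 unordered region pairs row-major over the
#' strict upper triangle: edge 1 = (1,2), edge 2 = (1,3), ..., edge M_G =
#' (r-1, r).
#'
#' @param atlas a [RegionAtlas-class] (or a single integer region count).
#' @return an [EdgeIndex-class] object.
#' @examples
#' ei <- buildEdgeIndex(84)
#' nrow(ei@pairs)  # 3486
#' @export
buildEdgeIndex <- function(atlas) {
  r <- if (is(atlas, "RegionAtlas")) nRegions(atlas) else as.integer(atlas)
  if (is.na(r) || r < 2L)
    stop("invalid atlas: need at least 2 regions to index edges")
  i <- rep.int(seq_len(r - 1L), times = (r - 1L):1L)
  j <- unlist(lapply(seq_len(r - 1L), function(a) (a + 1L):r), use.names = FALSE)
  new("EdgeIndex", r = r, pairs = cbind(i = as.integer(i), j = as.integer(j)))
}

#' @rdname nRegions
#' @export
setMethod("nRegions", "EdgeIndex", function(x) x@r)

#' Total number of edges of an edge index
#' @param index an [EdgeIndex-class].
#' @return M_G = r(r-1)/2.
#' @export
nEdges <- function(index) nrow(index@pairs)

#' Linear edge index of a region pair
#'
#' @param index an [EdgeIndex-class].
#' @param i,j region row indices (order-free; vectors allowed).
#' @return integer edge indices in 1..M_G.
#' @export
edgeToIndex <- function(index, i, j) {
  r <- index@r
  a <- pmin(i, j); b <- pmax(i, j)
  if (any(a < 1L | b > r | a == b)) stop("invalid region pair")
  as.integer((a - 1L) * r - a * (a - 1L) / 2L + (b - a))
}

#' Region pair of a linear edge index
#'
#' @param index an [EdgeIndex-class].
#' @param e edge indices in 1..M_G (vector allowed).
#' @return integer matrix with columns `i`, `j` (i < j).
#' @export
indexToEdge <- function(index, e) {
  if (any(e < 1L | e > nEdges(index))) stop("edge index out of range")
  index@pairs[e, , drop = FALSE]
}

setMethod("show", "EdgeIndex", function(object) {
  cat("EdgeIndex:", object@r, "regions,", nEdges(object), "edges\n")
})

#' Canonical cluster-pair label of an edge
#'
#' Returns the unordered lobe-pair label of an edge, canonicalized
#' alphabetically (e.g. the pair of a frontal and a temporal region is
#' `"Fro/Temp"` whichever way round the regions are given). With g cluster
#' labels there are g(g+1)/2 possible pair labels, same-cluster pairs
#' included.
#'
#' @param atlas a [RegionAtlas-class].
#' @param i,j region row indices or region ids (vectors allowed).
#' @return character vector of labels like `"Fro/Temp"`.
#' @export
clusterPairOfEdge <- function(atlas, i, j) {
  cl <- regionClusters(atlas)
  resolve <- function(x) {
    if (is.character(x)) {
      m <- match(x, regionIds(atlas))
      if (anyNA(m)) stop("unknown region id: ", paste(x[is.na(m)], collapse = ", "))
      m
    } else {
      x <- as.integer(x)
      if (any(x < 1L | x > length(cl))) stop("unknown region index")
      x
    }
  }
  a <- cl[resolve(i)]; b <- cl[resolve(j)]
  paste(pmin(a, b), pmax(a, b), sep = "/")
}

#' Cluster-pair label of every edge, in edge-index order
#'
#' @param atlas a [RegionAtlas-class].
#' @param index optional [EdgeIndex-class]; built from the atlas if omitted.
#' @return character vector of length M_G.
#' @export
edgeClusterPairs <- function(atlas, index = buildEdgeIndex(atlas)) {
  clusterPairOfEdge(atlas, index@pairs[, 1L], index@pairs[, 2L])
}

#' Mask edges between spatially adjacent regions
#'
#' Marks as missing every edge whose two regions are adjacent, leaving all
#' other entries bit-identical. Used to check whether the near-zero peak of
#' minimum-cost-path histograms is explained by adjacent region pairs.
#'
#' @param network a [ConnectivityNetwork-class].
#' @param adjacency symmetric 0/1 or logical r x r matrix, zero diagonal.
#' @return a [ConnectivityNetwork-class] with adjacent-pair edges masked.
#' @export
filterAdjacentEdges <- function(network, adjacency) {
  w <- network@weights
  adjacency <- matrix(as.logical(adjacency), nrow(adjacency), ncol(adjacency))
  if (!identical(dim(adjacency), dim(w)))
    stop("adjacency dimensions do not match the network")
  if (!identical(adjacency, t(adjacency)))
    stop("adjacency must be symmetric")
  diag(adjacency) <- FALSE
  m <- network@missing | adjacency
  initialize(network, missing = m)
}

#' Region adjacency from a label image
#'
#' Two regions are adjacent when any of their voxels share a face
#' (6-connectivity).
#'
#' @param labels 3D integer array; 0 = background, k > 0 = region k.
#' @param r region count (defaults to `max(labels)`).
#' @return symmetric logical r x r matrix with FALSE diagonal.
#' @export
adjacencyFromLabels <- function(labels, r = max(labels)) {
  d <- dim(labels)
  adj <- matrix(FALSE, r, r)
  note <- function(a, b) {
    keep <- a != b & a > 0L & b > 0L
    if (any(keep)) {
      ii <- cbind(a[keep], b[keep])
      adj[ii] <<- TRUE
      adj[ii[, 2:1, drop = FALSE]] <<- TRUE
    }
  }
  if (d[1] > 1) note(labels[-d[1], , , drop = FALSE], labels[-1, , , drop = FALSE])
  if (d[2] > 1) note(labels[, -d[2], , drop = FALSE], labels[, -1, , drop = FALSE])
  if (d[3] > 1) note(labels[, , -d[3], drop = FALSE], labels[, , -1, drop = FALSE])
  adj
}
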