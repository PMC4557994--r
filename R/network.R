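#' Construct a single-subject connectivity network
#'
#' @param weights symmetric r x r numeric matrix. NA entries are taken as
#'   missing in addition to `missing`.
#' @param kind one of `"DMC"`, `"DFA"`, `"fMT"`, `"fPC"`.
#' @param subjectId subject identifier.
#' @param missing optional symmetric logical matrix of masked edges.
#' @param regionIds optional region ids used as dimnames.
#' @return a [ConnectivityNetwork-class].
#' @export
ConnectivityNetwork <- function(weights, kind, subjectId = "subject",
                                missing = NULL, regionIds = NULL) {
  weights <- as.matrix(weights)
  if (is.null(missing)) missing <- matrix(FALSE, nrow(weights), ncol(weights))
  missing <- missing | is.na(weights) | t(is.na(weights))
  if (!is.null(regionIds)) dimnames(weights) <- list(regionIds, regionIds)
  new("ConnectivityNetwork", kind = kind, weights = weights,
      missing = missing, subjectId = as.character(subjectId))
}

#' @rdname networkKind
#' @export
setMethod("networkKind", "ConnectivityNetwork", function(x) x@kind)

#' @rdname netWeights
#' @export
setMethod("netWeights", "ConnectivityNetwork", function(x) {
  w <- x@weights
  w[x@missing] <- NA_real_
  w
})

#' @rdname missingMask
#' @export
setMethod("missingMask", "ConnectivityNetwork", function(x) x@missing)

#' @rdname nRegions
#' @export
setMethod("nRegions", "ConnectivityNetwork", function(x) nrow(x@weights))

setMethod("show", "ConnectivityNetwork", function(object) {
  r <- nRegions(object)
  off <- r * (r - 1L)
  miss <- object@missing
  diag(miss) <- FALSE
  cat(sprintf("ConnectivityNetwork [%s] subject '%s': %d regions, %d/%d edges masked\n",
              object@kind, object@subjectId, r, sum(miss) / 2L, off / 2L))
})

#' Extract the edge-weight vector of a network
#'
#' Flattens the strict upper triangle into the canonical edge order of
#' [buildEdgeIndex()] (masked edges become NA).
#'
#' @param network a [ConnectivityNetwork-class].
#' @param index optional [EdgeIndex-class].
#' @return numeric vector of length M_G.
#' @export
edgeVector <- function(network, index = buildEdgeIndex(nRegions(network))) {
  w <- netWeights(network)
  w[index@pairs]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [edgeVector()]: places the M_G values back into a symmetric
#' r x r matrix with NA diagonal.
#'
#' @param values numeric vector of length M_G in edge-index order.
#' @param index an [EdgeIndex-class].
#' @return symmetric numeric matrix.
#' @export
edgeVectorToMatrix <- function(values, index) {
  r <- index@r
  if (length(values) != nEdges(index)) stop("length(values) must equal M_G")
  m <- matrix(NA_real_, r, r)
  m[index@pairs] <- values
  m[index@pairs[, 2:1, drop = FALSE]] <- values
  m
}
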