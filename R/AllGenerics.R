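#' Number of regions
#' @param x a [RegionAtlas], [ConnectivityNetwork] or [EdgeIndex].
#' @return integer region count.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Region identifiers, in atlas order
#' @param x a [RegionAtlas].
#' @return character vector of region ids.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' Cluster (lobe) label of each region, in atlas order
#' @param x a [RegionAtlas].
#' @return character vector of cluster labels.
#' @export
setGeneric("regionClusters", function(x) standardGeneric("regionClusters"))

#' Network kind
#' @param x a [ConnectivityNetwork], [ConnectivityCohort] or [EdgeStats].
#' @return one of `"DMC"`, `"DFA"`, `"fMT"`, `"fPC"`.
#' @export
setGeneric("networkKind", function(x) standardGeneric("networkKind"))

#' Edge weight matrix
#' @param x a [ConnectivityNetwork].
#' @return symmetric numeric matrix (NA where masked).
#' @export
setGeneric("netWeights", function(x) standardGeneric("netWeights"))

#' Missing-edge mask
#' @param x a [ConnectivityNetwork].
#' @return symmetric logical matrix.
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' Per-edge statistics table
#' @param x an [EdgeStats].
#' @return data.frame, one row per edge.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
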