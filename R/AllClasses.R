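#' @import methods
#' @importFrom stats cor cov pchisq pf pnorm pt qt quantile rbinom rnorm runif sd setNames var
#' @importFrom utils read.delim write.table read.csv write.csv head tail
NULL

.NETWORK_KINDS <- c("DMC", "DFA", "fMT", "fPC")

#' Region atlas
#'
#' An ordered table of brain regions. The row order is fixed and defines the
#' row/column order of every connectivity matrix built against the atlas.
#' Each region carries a hemisphere tag (`L`, `R` or `none`) and a cluster
#' label (typically a lobe grouping such as `Sub`, `Occ`, `Par`, `Temp`,
#' `Fro`, `Cb`).
#'
#' @slot regions data.frame with columns `region_id`, `name`, `hemisphere`,
#'   `cluster`.
#' @export
setClass("RegionAtlas", slots = c(regions = "data.frame"))

setValidity("RegionAtlas", function(object) {
  df <- object@regions
  need <- c("region_id", "name", "hemisphere", "cluster")
  if (!all(need %in% names(df)))
    return(paste("regions must have columns:", paste(need, collapse = ", ")))
  if (nrow(df) < 1) return("atlas must contain at least one region")
  if (anyDuplicated(df$region_id)) return("region ids must be unique")
  if (!all(df$hemisphere %in% c("L", "R", "none")))
    return("hemisphere must be one of 'L', 'R', 'none'")
  if (any(is.na(df$cluster)) || any(!nzchar(df$cluster)))
    return("every region needs a non-empty cluster label")
  TRUE
})

#' Single-subject connectivity network
#'
#' A symmetric r x r matrix of edge weights for one subject and one network
#' kind, together with a symmetric logical mask of missing edges. Kinds:
#' `fMT` (Pearson correlation of mean time series), `fPC` (partial
#' correlation), `DMC` (minimum cumulative path cost), `DFA` (path FA per
#' Euclidean distance). The diagonal is never analysed.
#'
#' @slot kind one of `"DMC"`, `"DFA"`, `"fMT"`, `"fPC"`.
#' @slot weights symmetric numeric matrix, region order bound to an atlas.
#' @slot missing symmetric logical matrix marking masked edges.
#' @slot subjectId subject identifier.
#' @export
setClass("ConnectivityNetwork",
  slots = c(kind = "character", weights = "matrix",
            missing = "matrix", subjectId = "character"))

setValidity("ConnectivityNetwork", function(object) {
  w <- object@weights; m <- object@missing
  if (length(object@kind) != 1L || !object@kind %in% .NETWORK_KINDS)
    return(paste("kind must be one of", paste(.NETWORK_KINDS, collapse = ", ")))
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (!identical(dim(w), dim(m))) return("missing mask must match weights")
  if (!is.logical(m)) return("missing mask must be logical")
  if (!isTRUE(all.equal(m, t(m)))) return("missing mask must be symmetric")
  ok <- !m & !t(m)
  diag(ok) <- FALSE
  if (any(ok) && max(abs(w[ok] - t(w)[ok])) > 1e-8)
    return("weights must be symmetric on non-missing edges")
  vals <- w[ok]
  vals <- vals[is.finite(vals)]
  if (object@kind %in% c("fMT", "fPC") && length(vals) &&
      (min(vals) < -1 - 1e-8 || max(vals) > 1 + 1e-8))
    return("correlation weights must lie in [-1, 1]")
  if (object@kind == "DMC" && length(vals) && min(vals) < -1e-8)
    return("DMC weights must be non-negative")
  TRUE
})

#' Edge index
#'
#' Bijection between unordered region pairs (i, j), i < j, and linear edge
#' indices 1..M_G with M_G = r(r-1)/2, row-major over the strict upper
#' triangle. Edge 1 is pair (1, 2).
#'
#' @slot r region count.
#' @slot pairs integer matrix (M_G x 2) of region row indices, i < j.
#' @export
setClass("EdgeIndex", slots = c(r = "integer", pairs = "matrix"))

setValidity("EdgeIndex", function(object) {
  r <- object@r
  if (length(r) != 1L || is.na(r) || r < 2L)
    return("edge index requires at least two regions")
  if (nrow(object@pairs) != r * (r - 1L) / 2L)
    return("pair table must have r(r-1)/2 rows")
  TRUE
})

#' Voxel grid for structural network extraction
#'
#' Shared-shape 3D images: a non-negative local cost field, a fractional
#' anisotropy field in [0, 1], and an integer label image whose positive
#' values index regions of a [RegionAtlas]. Voxel size is in mm.
#'
#' @slot cost 3D numeric array, local traversal cost per voxel (>= 0).
#' @slot fa 3D numeric array, fractional anisotropy in [0, 1].
#' @slot labels 3D integer array; 0 = background, k > 0 = atlas region k.
#' @slot voxelSize numeric(3), voxel edge lengths (dx, dy, dz) in mm.
#' @export
setClass("VoxelGrid",
  slots = c(cost = "array", fa = "array", labels = "array",
            voxelSize = "numeric"))

setValidity("VoxelGrid", function(object) {
  if (!identical(dim(object@cost), dim(object@fa)) ||
      !identical(dim(object@cost), dim(object@labels)))
    return("cost, fa and labels must share shape")
  if (length(dim(object@cost)) != 3L) return("images must be 3D arrays")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths (mm)")
  if (any(object@cost < 0, na.rm = TRUE)) return("cost must be non-negative")
  if (any(object@fa < -1e-8 | object@fa > 1 + 1e-8, na.rm = TRUE))
    return("fa must lie in [0, 1]")
  TRUE
})

#' Multiple-testing correction record
#'
#' Holds the uncorrected level alpha, the raw test count M_G, the effective
#' number of independent tests M_eff, the adjusted threshold
#' alpha_adj = alpha / M_eff, and the worm-plot scale
#' s = log10(alpha) / log10(alpha_adj), which places an edge with
#' p = alpha_adj exactly on the height -log10(alpha).
#'
#' @slot alpha uncorrected significance level.
#' @slot mG raw number of edge tests, r(r-1)/2.
#' @slot mEff effective number of independent tests (1 <= mEff <= mG).
#' @slot alphaAdj adjusted per-edge threshold alpha / mEff.
#' @slot s worm-plot scale factor in (0, 1].
#' @export
setClass("CorrectionSpec",
  slots = c(alpha = "numeric", mG = "integer", mEff = "numeric",
            alphaAdj = "numeric", s = "numeric"))

setValidity("CorrectionSpec", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  if (object@mEff < 1) return("mEff must be >= 1")
  if (length(object@mG) && object@mEff > object@mG + 1e-8)
    return("mEff cannot exceed mG")
  if (abs(object@alphaAdj - object@alpha / object@mEff) > 1e-12)
    return("alphaAdj must equal alpha / mEff")
  TRUE
})

#' Per-edge group-difference statistics
#'
#' One row per edge: OLS coefficient for group membership (coded 0/1, so
#' positive t means group 1 > group 0), its t statistic and two-sided
#' p-value, the per-group edge means, and the number of subjects used.
#'
#' @slot table data.frame with columns `edge`, `region_a`, `region_b`,
#'   `cluster_pair`, `beta`, `t`, `p`, `mean0`, `mean1`, `n_used`, `df`.
#' @slot kind network kind the statistics were computed on.
#' @export
setClass("EdgeStats", slots = c(table = "data.frame", kind = "character"))

setValidity("EdgeStats", function(object) {
  need <- c("edge", "region_a", "region_b", "cluster_pair",
            "beta", "t", "p", "mean0", "mean1", "n_used", "df")
  if (!all(need %in% names(object@table)))
    return(paste("stats table must have columns:", paste(need, collapse = ", ")))
  p <- object@table$p
  if (any(is.finite(p) & (p < 0 | p > 1))) return("p-values must lie in [0, 1]")
  TRUE
})

#' Edge-by-subject cohort container
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `weights` is the M_G x n edge-by-subject matrix of one network kind
#' (NA = missing edge). `rowData` identifies each edge (regions and
#' lobe-pair cluster); `colData` is the subject table and must contain a
#' `group` column coded 0/1. The atlas and network kind live in `metadata`.
#'
#' @export
#' @import SummarizedExperiment
setClass("ConnectivityCohort", contains = "SummarizedExperiment")

setValidity("ConnectivityCohort", function(object) {
  if (!"weights" %in% SummarizedExperiment::assayNames(object))
    return("cohort needs a 'weights' assay")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% names(cd)) return("colData needs a 'group' column")
  g <- cd$group
  if (!all(g %in% c(0, 1))) return("group must be coded 0/1")
  if (ncol(object) < 4L) return("cohort needs at least 4 subjects")
  if (length(unique(g)) < 2L) return("both groups must be non-empty")
  if (!"kind" %in% names(S4Vectors::metadata(object)))
    return("metadata needs the network 'kind'")
  TRUE
})
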