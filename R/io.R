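#' Read / write a region atlas table
#'
#' TSV with header columns `region_id`, `name`, `hemisphere`, `cluster`;
#' row order defines matrix order.
#'
#' @param path file path.
#' @return [RegionAtlas-class] (read) / invisible path (write).
#' @export
readRegionAtlas <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  RegionAtlas(df)
}

#' @rdname readRegionAtlas
#' @param atlas a [RegionAtlas-class].
#' @export
writeRegionAtlas <- function(atlas, path) {
  write.table(atlas@regions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write a subject table
#'
#' TSV with columns `subject_id`, `group` (0/1) and covariates.
#'
#' @param path file path.
#' @return data.frame (read) / invisible path (write).
#' @export
readSubjectTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(df)))
    stop("subject table needs 'subject_id' and 'group' columns: ", path)
  df$subject_id <- as.character(df$subject_id)
  df
}

#' @rdname readSubjectTable
#' @param subjects data.frame.
#' @export
writeSubjectTable <- function(subjects, path) {
  write.table(subjects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a network as a square CSV
#'
#' Square matrix with region-id header and row names; masked edges are
#' empty cells.
#'
#' @param path file path.
#' @param kind network kind for the read result.
#' @param subjectId subject id for the read result.
#' @return [ConnectivityNetwork-class] (read) / invisible path (write).
#' @export
readNetworkCsv <- function(path, kind, subjectId = "subject") {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m))
    stop("malformed network file (", nrow(m), " rows x ", ncol(m),
         " columns): ", path)
  ConnectivityNetwork(m, kind, subjectId, regionIds = colnames(m))
}

#' @rdname readNetworkCsv
#' @param network a [ConnectivityNetwork-class].
#' @export
writeNetworkCsv <- function(network, path) {
  w <- netWeights(network)
  write.csv(w, path, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a network as a long edge TSV
#'
#' Canonical interchange format: columns `region_a`, `region_b`, `weight`,
#' one row per non-missing edge (i < j in atlas order). Robust to atlas
#' reordering because regions are named.
#'
#' @param path file path.
#' @param atlas the [RegionAtlas-class] defining region order.
#' @param kind,subjectId tags for the read result.
#' @return [ConnectivityNetwork-class] (read) / invisible path (write).
#' @export
readEdgeTsv <- function(path, atlas, kind, subjectId = "subject") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_a", "region_b", "weight")
  if (!all(need %in% names(df)))
    stop("malformed edge table (need columns ",
         paste(need, collapse = ", "), "): ", path)
  ids <- regionIds(atlas)
  ia <- match(df$region_a, ids); ib <- match(df$region_b, ids)
  if (anyNA(ia) || anyNA(ib))
    stop("edge table references regions missing from the atlas: ", path)
  r <- nRegions(atlas)
  m <- matrix(NA_real_, r, r, dimnames = list(ids, ids))
  m[cbind(ia, ib)] <- df$weight
  m[cbind(ib, ia)] <- df$weight
  diag(m) <- if (kind %in% c("fMT", "fPC")) 1 else 0
  ConnectivityNetwork(m, kind, subjectId, regionIds = ids)
}

#' @rdname readEdgeTsv
#' @param network a [ConnectivityNetwork-class].
#' @export
writeEdgeTsv <- function(network, path, atlas = NULL) {
  r <- nRegions(network)
  index <- buildEdgeIndex(r)
  ids <- if (!is.null(atlas)) regionIds(atlas) else rownames(network@weights)
  if (is.null(ids)) ids <- as.character(seq_len(r))
  v <- edgeVector(network, index)
  keep <- !is.na(v)
  df <- data.frame(region_a = ids[index@pairs[keep, 1L]],
                   region_b = ids[index@pairs[keep, 2L]],
                   weight = v[keep])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-subject time series
#'
#' TSV with one column per region (header = region ids in atlas order),
#' one row per timepoint.
#'
#' @param path file path.
#' @return T x r matrix (read) / invisible path (write).
#' @export
readTimeSeries <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE))
}

#' @rdname readTimeSeries
#' @param ts T x r matrix with region-id column names.
#' @export
writeTimeSeries <- function(ts, path) {
  write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the per-edge statistics table
#'
#' TSV mirror of [edgeTable()] plus the network kind.
#'
#' @param stats an [EdgeStats-class].
#' @param path file path.
#' @return invisible path (write) / [EdgeStats-class] (read).
#' @export
writeEdgeStats <- function(stats, path) {
  tab <- edgeTable(stats)
  tab <- cbind(kind = networkKind(stats), tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeStats
#' @export
readEdgeStats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  kind <- unique(df$kind)
  if (length(kind) != 1L) stop("stats table must hold one network kind: ", path)
  df$kind <- NULL
  new("EdgeStats", table = df, kind = kind)
}

#' Write a correction record as TSV
#'
#' @param correction a [CorrectionSpec-class].
#' @param kind network kind the correction belongs to.
#' @param path file path.
#' @export
writeCorrection <- function(correction, kind, path) {
  df <- data.frame(kind = kind, alpha = correction@alpha,
                   M_G = correction@mG, M_eff = correction@mEff,
                   alpha_adj = correction@alphaAdj, s = correction@s)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a voxel grid as NIfTI images
#'
#' Three NIfTI files share the grid: integer labels, FA and (optionally)
#' cost. Voxel size is taken from the label image header.
#'
#' @param labelPath,faPath,costPath NIfTI file paths; `costPath = NULL`
#'   derives the cost from FA via [defaultCostFromFA()].
#' @return a [VoxelGrid-class].
#' @export
readVoxelGrid <- function(labelPath, faPath, costPath = NULL) {
  lab <- RNifti::readNifti(labelPath)
  fa <- RNifti::readNifti(faPath)
  vs <- RNifti::pixdim(lab)[1:3]
  cost <- if (is.null(costPath)) defaultCostFromFA(array(as.numeric(fa), dim(fa)))
          else array(as.numeric(RNifti::readNifti(costPath)), dim(fa))
  VoxelGrid(array(as.integer(round(lab)), dim(lab)),
            array(as.numeric(fa), dim(fa)), cost = cost, voxelSize = vs)
}

#' @rdname readVoxelGrid
#' @param grid a [VoxelGrid-class].
#' @param prefix output path prefix; writes `<prefix>_labels.nii.gz`,
#'   `<prefix>_fa.nii.gz`, `<prefix>_cost.nii.gz`.
#' @export
writeVoxelGrid <- function(grid, prefix) {
  wr <- function(arr, suffix) {
    img <- RNifti::asNifti(arr, reference = NULL)
    RNifti::pixdim(img) <- grid@voxelSize
    RNifti::writeNifti(img, paste0(prefix, "_", suffix, ".nii.gz"))
  }
  wr(grid@labels, "labels"); wr(grid@fa, "fa"); wr(grid@cost, "cost")
  invisible(prefix)
}
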