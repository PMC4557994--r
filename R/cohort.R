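#' Assemble an edge-by-subject cohort
#'
#' Stacks one network kind across subjects into the M_G x n matrix that is
#' the unit of statistical analysis. Masked edges become NA.
#'
#' @param networks list of [ConnectivityNetwork-class] objects (one per
#'   subject, all the same kind and region count), or an M_G x n numeric
#'   matrix already in edge-index order.
#' @param subjects data.frame with columns `subject_id`, `group` (0/1) and
#'   any covariates; one row per subject, in the same order as `networks`.
#' @param atlas the [RegionAtlas-class] the networks are bound to.
#' @param kind network kind; inferred from the networks when omitted.
#' @return a [ConnectivityCohort-class].
#' @export
ConnectivityCohort <- function(networks, subjects, atlas, kind = NULL) {
  subjects <- as.data.frame(subjects)
  index <- buildEdgeIndex(atlas)
  if (is.list(networks) && !is.matrix(networks)) {
    kinds <- unique(vapply(networks, networkKind, ""))
    if (length(kinds) != 1L) stop("all networks must share one kind")
    if (is.null(kind)) kind <- kinds
    X <- vapply(networks, edgeVector, numeric(nEdges(index)), index = index)
  } else {
    X <- as.matrix(networks)
    if (nrow(X) != nEdges(index)) stop("weight matrix must have M_G rows")
    if (is.null(kind)) stop("kind must be given with a raw weight matrix")
  }
  if (ncol(X) != nrow(subjects))
    stop("subject table must have one row per network")
  ids <- regionIds(atlas)
  rd <- S4Vectors::DataFrame(
    edge = seq_len(nEdges(index)),
    region_a = ids[index@pairs[, 1L]],
    region_b = ids[index@pairs[, 2L]],
    cluster_pair = edgeClusterPairs(atlas, index))
  colnames(X) <- subjects$subject_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(weights = X), rowData = rd,
    colData = S4Vectors::DataFrame(subjects, row.names = subjects$subject_id),
    metadata = list(kind = kind, atlas = atlas))
  new("ConnectivityCohort", se)
}

#' @rdname networkKind
#' @export
setMethod("networkKind", "ConnectivityCohort",
          function(x) S4Vectors::metadata(x)$kind)

#' Atlas bound to a cohort
#' @param cohort a [ConnectivityCohort-class].
#' @return the [RegionAtlas-class] used to build it.
#' @export
cohortAtlas <- function(cohort) S4Vectors::metadata(cohort)$atlas

#' Edge-by-subject weight matrix of a cohort
#' @param cohort a [ConnectivityCohort-class].
#' @return M_G x n numeric matrix, NA = missing.
#' @export
edgeWeights <- function(cohort) SummarizedExperiment::assay(cohort, "weights")

#' Subject table of a cohort
#' @param cohort a [ConnectivityCohort-class].
#' @return data.frame with `subject_id`, `group` and covariates.
#' @export
subjectTable <- function(cohort)
  as.data.frame(SummarizedExperiment::colData(cohort))

#' Apply the missing-value policy to a cohort
#'
#' `exclude` (default) leaves missing entries masked, so each edge's
#' regression uses listwise deletion over its observed subjects.
#' `impute_group_mean` replaces each missing entry with the mean of that
#' edge over the observed subjects of the same group; entries missing for
#' an entire group stay masked.
#'
#' @param cohort a [ConnectivityCohort-class].
#' @param policy `"exclude"` or `"impute_group_mean"`.
#' @return a [ConnectivityCohort-class] with the policy applied.
#' @export
handleMissing <- function(cohort, policy = c("exclude", "impute_group_mean")) {
  policy <- match.arg(policy)
  if (policy == "exclude") return(cohort)
  X <- edgeWeights(cohort)
  g <- subjectTable(cohort)$group
  for (gv in c(0, 1)) {
    cols <- which(g == gv)
    sub <- X[, cols, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)  # NaN when whole group missing
    nas <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(nas)) {
      fill <- mu[nas[, 1L]]
      fill[!is.finite(fill)] <- NA_real_
      sub[nas] <- fill
      X[, cols] <- sub
    }
  }
  out <- cohort
  SummarizedExperiment::assay(out, "weights") <- X
  out
}

setMethod("show", "ConnectivityCohort", function(object) {
  g <- SummarizedExperiment::colData(object)$group
  cat(sprintf("ConnectivityCohort [%s]: %d edges x %d subjects (%d / %d per group), %d missing entries\n",
              networkKind(object), nrow(object), ncol(object),
              sum(g == 0), sum(g == 1), sum(is.na(edgeWeights(object)))))
})
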