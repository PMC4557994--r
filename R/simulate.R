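#' Synthetic lobe-structured atlas
#'
#' Builds a desk-scale atlas of `nClusters` lobe clusters with
#' `regionsPerCluster` regions each, alternating hemispheres.
#'
#' @param nClusters number of lobe clusters (default 5).
#' @param regionsPerCluster regions per cluster (default 6; r = 30).
#' @param clusterLabels labels to draw from (defaults to the conventional
#'   lobe groupings `Sub`, `Occ`, `Par`, `Temp`, `Fro`, `Cb`).
#' @return a [RegionAtlas-class].
#' @export
syntheticAtlas <- function(nClusters = 5L, regionsPerCluster = 6L,
                           clusterLabels = c("Sub", "Occ", "Par",
                                             "Temp", "Fro", "Cb")) {
  if (nClusters > length(clusterLabels))
    clusterLabels <- c(clusterLabels,
                       paste0("C", seq_len(nClusters - length(clusterLabels))))
  cl <- rep(clusterLabels[seq_len(nClusters)], each = regionsPerCluster)
  within <- rep(seq_len(regionsPerCluster), nClusters)
  hemi <- rep_len(c("L", "R"), length(cl))
  RegionAtlas(data.frame(
    region_id = paste0(cl, ".", hemi, within),
    name = paste(cl, "region", within, hemi),
    hemisphere = hemi, cluster = cl, stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Collects the parameters of the synthetic two-group cohort generators.
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: 5 clusters x 6 regions (r = 30), 30 + 30 subjects, T = 200
#' timepoints.
#'
#' @param seed RNG seed; the seed fully determines every generator output.
#' @param nClusters,regionsPerCluster atlas shape (see [syntheticAtlas()]).
#' @param n0,n1 group sizes (group 1 is the group of interest).
#' @param T timepoints per functional time series.
#' @param rhoWithin,rhoBetween target correlation inside / across clusters.
#' @param effectEdges which edges carry the group effect: a cluster-pair
#'   label such as `"Fro/Temp"`, or an integer vector of edge indices, or
#'   NULL for none.
#' @param effectSize standardized group effect. For the direct edge
#'   generator it is the mean shift in residual-SD units; for the
#'   time-series generator it is the shift of the edge correlation on the
#'   Fisher-z scale in units of the sampling SD 1/sqrt(T-3).
#' @param noiseSD residual SD of the direct edge generator.
#' @param covariateEffect coefficient (in residual-SD units) of the `age`
#'   covariate in the direct edge generator.
#' @param latentLoading loading (in residual-SD units) of a shared
#'   per-subject latent factor that correlates all edges (default 0:
#'   independent edges).
#' @param confounding shift of the `age` covariate mean in group 1, in SD
#'   units of age (default 0: no group-covariate confounding).
#' @param faBase,ridgeFA,faNoiseSD structural scene: background FA, FA on
#'   high-FA ridges, per-subject voxel noise SD.
#' @param faGroupScale multiplier applied to group-1 subjects' ridge FA
#'   (default 1: null scene).
#' @param voxelSize voxel size of the scene in mm.
#' @return a validated configuration list of class `simulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, nClusters = 5L, regionsPerCluster = 6L,
                             n0 = 30L, n1 = 30L, T = 200L,
                             rhoWithin = 0.3, rhoBetween = 0.05,
                             effectEdges = NULL, effectSize = 0,
                             noiseSD = 0.1, covariateEffect = 0.2,
                             latentLoading = 0, confounding = 0,
                             faBase = 0.2, ridgeFA = 0.8, faNoiseSD = 0.05,
                             faGroupScale = 1, voxelSize = c(1, 1, 1)) {
  cfg <- list(seed = as.integer(seed), nClusters = as.integer(nClusters),
              regionsPerCluster = as.integer(regionsPerCluster),
              n0 = as.integer(n0), n1 = as.integer(n1), T = as.integer(T),
              rhoWithin = rhoWithin, rhoBetween = rhoBetween,
              effectEdges = effectEdges, effectSize = effectSize,
              noiseSD = noiseSD, covariateEffect = covariateEffect,
              latentLoading = latentLoading, confounding = confounding,
              faBase = faBase, ridgeFA = ridgeFA, faNoiseSD = faNoiseSD,
              faGroupScale = faGroupScale, voxelSize = voxelSize)
  if (cfg$n0 < 2L || cfg$n1 < 2L) stop("both groups need at least 2 subjects")
  if (cfg$T < 4L) stop("need at least 4 timepoints")
  if (abs(cfg$rhoWithin) >= 1 || abs(cfg$rhoBetween) >= 1)
    stop("correlations must lie in (-1, 1)")
  class(cfg) <- "simulationConfig"
  cfg
}

# Resolve an effect-edge specifier to edge indices.
.resolveEffectEdges <- function(effectEdges, atlas, index) {
  if (is.null(effectEdges)) return(integer(0))
  if (is.character(effectEdges)) {
    cp <- edgeClusterPairs(atlas, index)
    hits <- which(cp %in% effectEdges)
    if (!length(hits)) stop("no edges match cluster pair(s): ",
                            paste(effectEdges, collapse = ", "))
    hits
  } else as.integer(effectEdges)
}

.subjectTableFor <- function(cfg) {
  n <- cfg$n0 + cfg$n1
  group <- rep(c(0L, 1L), c(cfg$n0, cfg$n1))
  data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    group = group,
    age = rnorm(n, mean = 0, sd = 1) + cfg$confounding * group,
    sex = rbinom(n, 1L, 0.5),
    stringsAsFactors = FALSE)
}

#' Simulate a two-group functional time-series cohort
#'
#' Each subject's T x r series is drawn from a zero-mean multivariate
#' normal with block-structured correlation (`rhoWithin` inside clusters,
#' `rhoBetween` across). In group 1 the correlations of the effect edges
#' are shifted on the Fisher-z scale by
#' `effectSize / sqrt(T - 3)` (i.e. `effectSize` sampling SDs of a
#' subject-level z-transformed correlation). Covariates are drawn per
#' config, with optional group confounding of `age`.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `timeSeries` (per-subject T x r matrices), `subjects`
#'   (subject table), `atlas`, `effectEdges` (indices), `targetCor`
#'   (per-group target correlation matrices) and `config`.
#' @export
simulateTimeseriesCohort <- function(cfg = simulationConfig()) {
  set.seed(cfg$seed)
  atlas <- syntheticAtlas(cfg$nClusters, cfg$regionsPerCluster)
  r <- nRegions(atlas)
  index <- buildEdgeIndex(atlas)
  cl <- regionClusters(atlas)
  C0 <- matrix(cfg$rhoBetween, r, r)
  for (lab in unique(cl)) {
    idx <- which(cl == lab)
    C0[idx, idx] <- cfg$rhoWithin
  }
  diag(C0) <- 1
  eff <- .resolveEffectEdges(cfg$effectEdges, atlas, index)
  C1 <- C0
  if (length(eff)) {
    dz <- cfg$effectSize / sqrt(cfg$T - 3)
    pr <- index@pairs[eff, , drop = FALSE]
    z <- atanh(C1[pr]) + dz
    C1[pr] <- tanh(z)
    C1[pr[, 2:1, drop = FALSE]] <- tanh(z)
  }
  for (nm in c("group 0", "group 1")) {
    C <- if (nm == "group 0") C0 else C1
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10)
      stop("target correlation for ", nm, " is not positive definite ",
           "(min eigenvalue ", signif(ev, 3),
           "); reduce rhoWithin/rhoBetween or the effect size")
  }
  subjects <- .subjectTableFor(cfg)
  R0 <- chol(C0); R1 <- chol(C1)
  ts <- lapply(seq_len(nrow(subjects)), function(s) {
    R <- if (subjects$group[s] == 1) R1 else R0
    m <- matrix(rnorm(cfg$T * r), cfg$T, r) %*% R
    colnames(m) <- regionIds(atlas)
    m
  })
  names(ts) <- subjects$subject_id
  list(timeSeries = ts, subjects = subjects, atlas = atlas,
       effectEdges = eff, targetCor = list(group0 = C0, group1 = C1),
       config = cfg)
}

#' Simulate a two-group edge cohort directly
#'
#' Skips time series and images: edge weights are
#' `w = mu_e + beta_e * group + gamma * age + lambda * u_subject + eps`,
#' with `beta_e = effectSize * noiseSD` on the effect edges and zero
#' elsewhere, `gamma = covariateEffect * noiseSD`, an optional shared
#' latent factor `u` (loading `latentLoading * noiseSD`) that correlates
#' edges, and iid Gaussian noise with SD `noiseSD`. Baseline `mu_e` is
#' 0.4 for within-cluster edges and 0.1 across clusters. Used for fast
#' calibration, power and M_eff experiments.
#'
#' @param cfg a [simulationConfig()].
#' @param kind network kind tag of the produced cohort (default `"fMT"`).
#' @return list with `cohort` (a [ConnectivityCohort-class]), `atlas`,
#'   `effectEdges`, `beta` (true per-edge group effects) and `config`.
#' @export
simulateEdgeCohort <- function(cfg = simulationConfig(), kind = "fMT") {
  set.seed(cfg$seed)
  atlas <- syntheticAtlas(cfg$nClusters, cfg$regionsPerCluster)
  index <- buildEdgeIndex(atlas)
  M <- nEdges(index)
  cp <- edgeClusterPairs(atlas, index)
  same <- vapply(strsplit(cp, "/", fixed = TRUE),
                 function(x) x[1] == x[2], TRUE)
  mu <- ifelse(same, 0.4, 0.1)
  eff <- .resolveEffectEdges(cfg$effectEdges, atlas, index)
  beta <- numeric(M)
  beta[eff] <- cfg$effectSize * cfg$noiseSD
  subjects <- .subjectTableFor(cfg)
  n <- nrow(subjects)
  gamma <- cfg$covariateEffect * cfg$noiseSD
  u <- rnorm(n)
  X <- mu + outer(beta, subjects$group) +
    outer(rep(gamma, M), subjects$age) +
    cfg$latentLoading * cfg$noiseSD * matrix(u, M, n, byrow = TRUE) +
    matrix(rnorm(M * n, sd = cfg$noiseSD), M, n)
  cohort <- ConnectivityCohort(X, subjects, atlas, kind = kind)
  list(cohort = cohort, atlas = atlas, effectEdges = eff, beta = beta,
       config = cfg)
}

# Region layout of the structural scene: single-voxel regions on a 2D
# lattice with one-voxel gaps, in a 3-slice slab.
.sceneLayout <- function(r, voxelSize) {
  cols <- ceiling(sqrt(r))
  rows <- ceiling(r / cols)
  dims <- c(2L * cols + 1L, 2L * rows + 1L, 3L)
  pos <- cbind(
    x = 2L * ((seq_len(r) - 1L) %% cols) + 2L,
    y = 2L * ((seq_len(r) - 1L) %/% cols) + 2L,
    z = 2L)
  if (anyDuplicated(pos)) stop("region layout overlaps; enlarge the grid")
  labels <- array(0L, dims)
  labels[pos] <- seq_len(r)
  list(dims = dims, pos = pos, labels = labels)
}

# Straight voxel line between two scene positions (inclusive).
.voxelLine <- function(a, b) {
  nstep <- max(abs(b - a)) + 1L
  tseq <- seq(0, 1, length.out = max(nstep, 2L))
  unique(round(cbind(a[1] + tseq * (b[1] - a[1]),
                     a[2] + tseq * (b[2] - a[2]),
                     a[3] + tseq * (b[3] - a[3]))))
}

#' Simulate a two-group structural scene
#'
#' Builds per-subject [VoxelGrid-class]s: regions laid out as spatial
#' blocks in a small slab, a smooth FA field with high-FA ridges along the
#' straight lines joining designated region pairs, and per-subject voxel
#' noise. Group-1 subjects have their ridge FA multiplied by
#' `faGroupScale`; under the default cost c = 1 - FA, lowering ridge FA
#' raises that pair's minimum path cost (DMC up, DFA down).
#'
#' @param cfg a [simulationConfig()].
#' @return list with `grids` (per-subject [VoxelGrid-class]), `subjects`,
#'   `atlas`, `ridgeEdges` (edge indices carrying ridges) and `config`.
#' @export
simulateStructuralScene <- function(cfg = simulationConfig()) {
  set.seed(cfg$seed)
  atlas <- syntheticAtlas(cfg$nClusters, cfg$regionsPerCluster)
  r <- nRegions(atlas)
  index <- buildEdgeIndex(atlas)
  lay <- .sceneLayout(r, cfg$voxelSize)
  eff <- .resolveEffectEdges(cfg$effectEdges, atlas, index)
  # ridges along every within-cluster pair plus the designated effect edges
  cp <- edgeClusterPairs(atlas, index)
  same <- vapply(strsplit(cp, "/", fixed = TRUE),
                 function(x) x[1] == x[2], TRUE)
  ridgeEdges <- sort(unique(c(which(same), eff)))
  ridgeMask <- array(FALSE, lay$dims)
  effMask <- array(FALSE, lay$dims)
  for (e in ridgeEdges) {
    pr <- index@pairs[e, ]
    line <- .voxelLine(lay$pos[pr[1], ], lay$pos[pr[2], ])
    ridgeMask[line] <- TRUE
    if (e %in% eff) effMask[line] <- TRUE
  }
  baseFA <- array(cfg$faBase, lay$dims)
  baseFA[ridgeMask] <- cfg$ridgeFA
  subjects <- .subjectTableFor(cfg)
  grids <- lapply(seq_len(nrow(subjects)), function(s) {
    fa <- baseFA
    if (subjects$group[s] == 1 && cfg$faGroupScale != 1)
      fa[effMask] <- fa[effMask] * cfg$faGroupScale
    fa <- fa + array(rnorm(prod(lay$dims), sd = cfg$faNoiseSD), lay$dims)
    fa <- pmin(pmax(fa, 0), 1)
    VoxelGrid(lay$labels, fa, voxelSize = cfg$voxelSize)
  })
  names(grids) <- subjects$subject_id
  list(grids = grids, subjects = subjects, atlas = atlas,
       ridgeEdges = ridgeEdges, effectEdges = eff, config = cfg)
}
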