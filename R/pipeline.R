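#' @name pipeline
#' @title File-based analysis pipeline
#'
#' @description Stage functions mirroring the end-to-end workflow: simulate
#' a cohort (or start from your own files in the same layout), build
#' functional and structural networks, run the per-edge statistics with
#' M_eff-corrected thresholds, and emit machine-readable plot data. Each
#' stage reads the previous stage's outputs from `outdir` and fails with
#' the name of the missing stage if run out of order. [runPipeline()] runs
#' everything.
#'
#' Layout under `outdir`: `inputs/` (atlas, subjects, time series, scene
#' images), `networks/<kind>/` (per-subject edge TSVs), `tables/`
#' (stats, correction, cluster shifts), `figures/` (plot-data JSON),
#' `manifest.yaml`, `run.log`.
NULL

.pipePaths <- function(outdir) {
  list(inputs = file.path(outdir, "inputs"),
       ts = file.path(outdir, "inputs", "timeseries"),
       scene = file.path(outdir, "inputs", "scene"),
       networks = file.path(outdir, "networks"),
       tables = file.path(outdir, "tables"),
       figures = file.path(outdir, "figures"),
       atlas = file.path(outdir, "inputs", "atlas.tsv"),
       subjects = file.path(outdir, "inputs", "subjects.tsv"),
       manifest = file.path(outdir, "manifest.yaml"),
       log = file.path(outdir, "run.log"))
}

.pipeLog <- function(outdir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  message(msg)
  cat(msg, "\n", file = .pipePaths(outdir)$log, append = TRUE)
}

.needStage <- function(path, stage) {
  if (!file.exists(path))
    stop("missing '", path, "': run the '", stage, "' stage first")
}

#' @rdname pipeline
#' @param cfg a [simulationConfig()].
#' @param outdir output directory (created if needed).
#' @export
pipelineSimulate <- function(cfg, outdir) {
  p <- .pipePaths(outdir)
  for (d in c(p$inputs, p$ts, p$scene)) dir.create(d, recursive = TRUE,
                                                   showWarnings = FALSE)
  fun <- simulateTimeseriesCohort(cfg)
  writeRegionAtlas(fun$atlas, p$atlas)
  writeSubjectTable(fun$subjects, p$subjects)
  for (id in names(fun$timeSeries))
    writeTimeSeries(fun$timeSeries[[id]], file.path(p$ts, paste0(id, ".tsv")))
  scn <- simulateStructuralScene(cfg)
  for (id in names(scn$grids))
    writeVoxelGrid(scn$grids[[id]], file.path(p$scene, id))
  .pipeLog(outdir, "simulate: ", length(fun$timeSeries), " subjects, r=",
           nRegions(fun$atlas))
  invisible(outdir)
}

#' @rdname pipeline
#' @export
pipelineBuildFunctional <- function(outdir) {
  p <- .pipePaths(outdir)
  .needStage(p$atlas, "simulate")
  atlas <- readRegionAtlas(p$atlas)
  subjects <- readSubjectTable(p$subjects)
  for (kind in c("fMT", "fPC"))
    dir.create(file.path(p$networks, kind), recursive = TRUE,
               showWarnings = FALSE)
  for (id in subjects$subject_id) {
    f <- file.path(p$ts, paste0(id, ".tsv"))
    .needStage(f, "simulate")
    ts <- readTimeSeries(f)
    writeEdgeTsv(pearsonNetwork(ts, id),
                 file.path(p$networks, "fMT", paste0(id, ".tsv")), atlas)
    writeEdgeTsv(partialCorrelationNetwork(ts, id),
                 file.path(p$networks, "fPC", paste0(id, ".tsv")), atlas)
  }
  .pipeLog(outdir, "build-functional: fMT + fPC for ",
           nrow(subjects), " subjects")
  invisible(outdir)
}

#' @rdname pipeline
#' @export
pipelineBuildStructural <- function(outdir) {
  p <- .pipePaths(outdir)
  .needStage(p$atlas, "simulate")
  atlas <- readRegionAtlas(p$atlas)
  subjects <- readSubjectTable(p$subjects)
  for (kind in c("DMC", "DFA"))
    dir.create(file.path(p$networks, kind), recursive = TRUE,
               showWarnings = FALSE)
  for (id in subjects$subject_id) {
    lf <- file.path(p$scene, paste0(id, "_labels.nii.gz"))
    .needStage(lf, "simulate")
    grid <- readVoxelGrid(lf, file.path(p$scene, paste0(id, "_fa.nii.gz")),
                          file.path(p$scene, paste0(id, "_cost.nii.gz")))
    nets <- minCostPathNetwork(grid, atlas, subjectId = id, keepPaths = FALSE)
    writeEdgeTsv(nets$dmc,
                 file.path(p$networks, "DMC", paste0(id, ".tsv")), atlas)
    writeEdgeTsv(nets$dfa,
                 file.path(p$networks, "DFA", paste0(id, ".tsv")), atlas)
  }
  .pipeLog(outdir, "build-structural: DMC + DFA for ",
           nrow(subjects), " subjects")
  invisible(outdir)
}

#' Load one network kind back into a cohort
#'
#' @param outdir pipeline output directory.
#' @param kind network kind subdirectory to load.
#' @return a [ConnectivityCohort-class].
#' @export
loadCohort <- function(outdir, kind) {
  p <- .pipePaths(outdir)
  .needStage(p$atlas, "simulate")
  atlas <- readRegionAtlas(p$atlas)
  subjects <- readSubjectTable(p$subjects)
  nets <- lapply(subjects$subject_id, function(id) {
    f <- file.path(p$networks, kind, paste0(id, ".tsv"))
    .needStage(f, if (kind %in% c("fMT", "fPC")) "build-functional"
                  else "build-structural")
    readEdgeTsv(f, atlas, kind, id)
  })
  ConnectivityCohort(nets, subjects, atlas, kind = kind)
}

#' @rdname pipeline
#' @param kinds network kinds to analyse.
#' @param covariates covariate columns of the subject table to adjust for.
#' @param alpha uncorrected significance level.
#' @param missingPolicy `"exclude"` or `"impute_group_mean"` (see
#'   [handleMissing()]).
#' @export
pipelineStats <- function(outdir, kinds = c("fMT", "fPC", "DMC", "DFA"),
                          covariates = c("age", "sex"), alpha = 0.05,
                          missingPolicy = "exclude") {
  p <- .pipePaths(outdir)
  dir.create(p$tables, recursive = TRUE, showWarnings = FALSE)
  .needStage(p$subjects, "simulate")
  subjects <- readSubjectTable(p$subjects)
  bad <- setdiff(covariates, names(subjects))
  if (length(bad))
    stop("unknown covariate(s) in config: ", paste(bad, collapse = ", "))
  for (kind in kinds) {
    cohort <- handleMissing(loadCohort(outdir, kind), missingPolicy)
    st <- edgeRegression(cohort, covariates)
    mEff <- effectiveNumberOfTests(cohort)
    corr <- correctionSpec(mG = nrow(cohort), mEff = mEff, alpha = alpha)
    writeEdgeStats(st, file.path(p$tables, paste0("stats_", kind, ".tsv")))
    writeCorrection(corr, kind,
                    file.path(p$tables, paste0("correction_", kind, ".tsv")))
    sh <- clusterShiftTests(st)
    write.table(sh, file.path(p$tables, paste0("cluster_shift_", kind, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .pipeLog(outdir, "stats[", kind, "]: M_eff=", round(mEff, 2),
             ", alpha_adj=", signif(corr@alphaAdj, 3),
             ", significant edges=", sum(edgeTable(st)$p < corr@alphaAdj,
                                         na.rm = TRUE))
  }
  invisible(outdir)
}

.readCorrection <- function(path) {
  df <- read.delim(path)
  correctionSpec(mG = df$M_G, mEff = df$M_eff, alpha = df$alpha)
}

#' @rdname pipeline
#' @export
pipelinePlots <- function(outdir, kinds = c("fMT", "fPC", "DMC", "DFA")) {
  p <- .pipePaths(outdir)
  dir.create(p$figures, recursive = TRUE, showWarnings = FALSE)
  .needStage(p$atlas, "simulate")
  atlas <- readRegionAtlas(p$atlas)
  statsList <- list(); cohorts <- list()
  for (kind in kinds) {
    sf <- file.path(p$tables, paste0("stats_", kind, ".tsv"))
    .needStage(sf, "stats")
    st <- readEdgeStats(sf)
    corr <- .readCorrection(file.path(p$tables,
                                      paste0("correction_", kind, ".tsv")))
    statsList[[kind]] <- st
    worm <- wormPlotData(st, corr)
    jsonlite::write_json(
      list(reference = attr(worm, "reference"),
           clusters = attr(worm, "clusters"), points = worm),
      file.path(p$figures, paste0("worm_", kind, ".json")),
      digits = NA, auto_unbox = TRUE)
    cg <- connectogramData(st, corr, atlas)
    jsonlite::write_json(cg, file.path(p$figures,
                                       paste0("connectogram_", kind, ".json")),
                         digits = NA, auto_unbox = TRUE)
    cohorts[[kind]] <- loadCohort(outdir, kind)
  }
  bm <- bimodalPlotData(cohorts, mode = "group_means")
  jsonlite::write_json(bm, file.path(p$figures, "bimodal_means.json"),
                       digits = NA, auto_unbox = TRUE)
  bt <- bimodalPlotData(cohorts, mode = "t_stats", statsList = statsList)
  jsonlite::write_json(bt, file.path(p$figures, "bimodal_t.json"),
                       digits = NA, auto_unbox = TRUE)
  .pipeLog(outdir, "plots: worm/connectogram per kind + bimodal grids")
  invisible(outdir)
}

#' Run the whole pipeline on a synthetic cohort
#'
#' Simulate -> build functional and structural networks -> per-edge
#' statistics with M_eff-adjusted thresholds and cluster shift tests ->
#' plot data. Fully deterministic given `cfg$seed`: repeated runs write
#' byte-identical tables. A `manifest.yaml` (seed, config, package
#' version, input hashes) is written alongside.
#'
#' @param cfg a [simulationConfig()].
#' @param outdir output directory.
#' @inheritParams pipelineStats
#' @return invisible `outdir`.
#' @export
runPipeline <- function(cfg = simulationConfig(), outdir,
                        kinds = c("fMT", "fPC", "DMC", "DFA"),
                        covariates = c("age", "sex"), alpha = 0.05,
                        missingPolicy = "exclude") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- .pipePaths(outdir)
  pipelineSimulate(cfg, outdir)
  pipelineBuildFunctional(outdir)
  pipelineBuildStructural(outdir)
  pipelineStats(outdir, kinds, covariates, alpha, missingPolicy)
  pipelinePlots(outdir, kinds)
  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
    alpha = alpha, covariates = covariates,
    missing_policy = missingPolicy, kinds = kinds,
    package_version = as.character(utils::packageVersion("conncompare")),
    input_md5 = {
      h <- tools::md5sum(c(p$atlas, p$subjects))
      as.list(setNames(unname(h), basename(names(h))))
    })
  yaml::write_yaml(manifest, p$manifest)
  .pipeLog(outdir, "run-all complete")
  invisible(outdir)
}
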