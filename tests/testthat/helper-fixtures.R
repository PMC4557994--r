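# Small in-code fixtures shared across tests.

tinyAtlas <- function(n = 4, clusters = c("Fro", "Fro", "Temp", "Occ")) {
  RegionAtlas(data.frame(
    region_id = paste0("r", seq_len(n)),
    name = paste("region", seq_len(n)),
    hemisphere = rep_len(c("L", "R"), n),
    cluster = rep_len(clusters, n),
    stringsAsFactors = FALSE))
}

twoRegionAtlas <- function() {
  RegionAtlas(data.frame(region_id = c("A", "B"), name = c("A", "B"),
                         hemisphere = c("L", "R"), cluster = c("X", "X")))
}

# Cohort with hand-chosen per-edge values: weights is M_G x n.
makeCohort <- function(weights, group, atlas = NULL, kind = "fMT",
                       covariates = NULL) {
  n <- length(group)
  if (is.null(atlas)) {
    r <- ceiling((1 + sqrt(1 + 8 * nrow(weights))) / 2)
    atlas <- tinyAtlas(r, rep_len(c("Fro", "Temp"), r))
  }
  subj <- data.frame(subject_id = sprintf("s%02d", seq_len(n)), group = group)
  if (!is.null(covariates)) subj <- cbind(subj, covariates)
  ConnectivityCohort(weights, subj, atlas, kind = kind)
}

# Minimal EdgeStats with given t and p, all in one or more clusters.
makeEdgeStats <- function(t, p, cluster = "Fro/Temp", kind = "fMT") {
  m <- length(t)
  tab <- data.frame(
    edge = seq_len(m), region_a = paste0("a", seq_len(m)),
    region_b = paste0("b", seq_len(m)),
    cluster_pair = rep_len(cluster, m),
    beta = t, t = t, p = p, mean0 = 0, mean1 = t,
    n_used = 60L, df = 56, stringsAsFactors = FALSE)
  new("EdgeStats", table = tab, kind = kind)
}
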