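#' Worm-plot point data
#'
#' Builds the deterministic point layout of a worm plot: edges grouped by
#' lobe-pair cluster, sorted ascending by t within each cluster (ties
#' broken by edge index), evenly spaced on x, with
#' y = -log10(p) * sign(t) * s. The scale s (from the
#' [CorrectionSpec-class]) places an edge with p = alpha_adj exactly at
#' |y| = -log10(alpha), so the same reference line height serves every
#' network kind.
#'
#' @param stats an [EdgeStats-class].
#' @param correction a [CorrectionSpec-class].
#' @return data.frame with columns `cluster_pair`, `edge`, `t`, `p`,
#'   `within_index`, `x`, `y`; attributes `reference` (-log10(alpha)) and
#'   `clusters` (cluster order on the x axis).
#' @export
wormPlotData <- function(stats, correction) {
  tab <- edgeTable(stats)
  tab <- tab[is.finite(tab$t) & is.finite(tab$p), , drop = FALSE]
  if (any(tab$p == 0)) {
    warning("p-value underflow clipped to smallest positive double")
    tab$p[tab$p == 0] <- .Machine$double.xmin
  }
  s <- correction@s
  clusters <- sort(unique(tab$cluster_pair))
  out <- lapply(seq_along(clusters), function(ci) {
    sub <- tab[tab$cluster_pair == clusters[ci], , drop = FALSE]
    ord <- order(sub$t, sub$edge)
    sub <- sub[ord, , drop = FALSE]
    kk <- nrow(sub)
    data.frame(cluster_pair = sub$cluster_pair, edge = sub$edge,
               t = sub$t, p = sub$p,
               within_index = seq_len(kk),
               x = (ci - 1) + (seq_len(kk) - 0.5) / kk,
               y = -log10(sub$p) * sign(sub$t) * s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "reference") <- -log10(correction@alpha)
  attr(out, "clusters") <- clusters
  out
}

# One shared histogram: counts of x per group on fixed break points.
.groupHist <- function(x, g, breaks) {
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  cut0 <- findInterval(x[g == 0], breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
  cut1 <- findInterval(x[g == 1], breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
  data.frame(bin = seq_along(mids), mid = mids,
             lo = breaks[-length(breaks)], hi = breaks[-1],
             count0 = tabulate(cut0, length(mids)),
             count1 = tabulate(cut1, length(mids)))
}

#' Bi-modal network comparison plot data
#'
#' Computes the 1D (per network kind) and 2D (per structural x functional
#' kind pair) histograms behind a bi-modal comparison plot.
#'
#' In `group_means` mode each histogram is built from the per-group mean
#' edge weights, with both groups binned on shared edges; a 2D bin's
#' rendering mixes blue (pure group 1: the group of interest) and red
#' (pure group 0) into magenta in proportion to the group mix, with
#' opacity proportional to the max-normalized total count. In `t_stats`
#' mode single green histograms of the edge t statistics are produced.
#'
#' @param cohorts named list of [ConnectivityCohort-class] objects (names
#'   are the network kinds), all built on the same atlas.
#' @param mode `"group_means"` or `"t_stats"`.
#' @param statsList named list of [EdgeStats-class] matching `cohorts`
#'   (required in `t_stats` mode; computed with no covariates if omitted).
#' @param bins1d number of 1D bins (default 100).
#' @param bins2d number of bins per axis of the 2D histograms (default 64).
#' @return list with `marginal` (per-kind histogram data.frame), `joint`
#'   (per structural x functional pair bin table with per-group counts and
#'   RGBA), and `mode`.
#' @export
bimodalPlotData <- function(cohorts, mode = c("group_means", "t_stats"),
                            statsList = NULL, bins1d = 100L, bins2d = 64L) {
  mode <- match.arg(mode)
  if (bins1d < 2L || bins2d < 2L) stop("need at least 2 bins")
  kinds <- names(cohorts)
  structural <- intersect(kinds, c("DMC", "DFA"))
  functional <- intersect(kinds, c("fMT", "fPC"))

  edgeVals <- lapply(kinds, function(k) {
    if (mode == "group_means") {
      X <- edgeWeights(cohorts[[k]])
      g <- subjectTable(cohorts[[k]])$group
      m0 <- rowMeans(X[, g == 0, drop = FALSE], na.rm = TRUE)
      m1 <- rowMeans(X[, g == 1, drop = FALSE], na.rm = TRUE)
      m0[!is.finite(m0)] <- NA; m1[!is.finite(m1)] <- NA
      list(v0 = m0, v1 = m1)
    } else {
      st <- if (!is.null(statsList)) statsList[[k]] else edgeRegression(cohorts[[k]])
      list(t = edgeTable(st)$t)
    }
  })
  names(edgeVals) <- kinds

  marginal <- lapply(kinds, function(k) {
    ev <- edgeVals[[k]]
    if (mode == "group_means") {
      vals <- c(ev$v0, ev$v1)
      gg <- rep(c(0, 1), c(length(ev$v0), length(ev$v1)))
      ok <- is.finite(vals)
      breaks <- seq(min(vals[ok]), max(vals[ok]), length.out = bins1d + 1L)
      h <- .groupHist(vals[ok], gg[ok], breaks)
      cbind(kind = k, h)
    } else {
      tv <- ev$t[is.finite(ev$t)]
      breaks <- seq(min(tv), max(tv), length.out = bins1d + 1L)
      h <- .groupHist(tv, rep(0, length(tv)), breaks)
      h$count <- h$count0; h$count0 <- NULL; h$count1 <- NULL
      cbind(kind = k, h, color = "green")
    }
  })
  names(marginal) <- kinds

  joint <- list()
  for (sk in structural) for (fk in functional) {
    pairName <- paste(sk, fk, sep = "x")
    if (mode == "group_means") {
      tabs <- lapply(c(0, 1), function(gi) {
        xs <- if (gi == 0) edgeVals[[sk]]$v0 else edgeVals[[sk]]$v1
        ys <- if (gi == 0) edgeVals[[fk]]$v0 else edgeVals[[fk]]$v1
        ok <- is.finite(xs) & is.finite(ys)
        cbind(xs[ok], ys[ok])
      })
      allx <- c(tabs[[1]][, 1], tabs[[2]][, 1])
      ally <- c(tabs[[1]][, 2], tabs[[2]][, 2])
      bx <- seq(min(allx), max(allx), length.out = bins2d + 1L)
      by <- seq(min(ally), max(ally), length.out = bins2d + 1L)
      cnt <- lapply(tabs, function(m) {
        ix <- findInterval(m[, 1], bx, rightmost.closed = TRUE, all.inside = TRUE)
        iy <- findInterval(m[, 2], by, rightmost.closed = TRUE, all.inside = TRUE)
        matrix(tabulate((iy - 1L) * bins2d + ix, bins2d * bins2d),
               bins2d, bins2d)
      })
      total <- cnt[[1]] + cnt[[2]]
      nz <- which(total > 0, arr.ind = TRUE)
      f0 <- cnt[[1]][nz] / total[nz]
      f1 <- cnt[[2]][nz] / total[nz]
      mx <- pmax(f0, f1)
      grid <- data.frame(
        xbin = nz[, 1], ybin = nz[, 2],
        count0 = cnt[[1]][nz], count1 = cnt[[2]][nz],
        r = f0 / mx, g = 0, b = f1 / mx,
        alpha = total[nz] / max(total))
      joint[[pairName]] <- list(structural = sk, functional = fk,
                                xbreaks = bx, ybreaks = by, bins = grid)
    } else {
      xs <- edgeVals[[sk]]$t; ys <- edgeVals[[fk]]$t
      ok <- is.finite(xs) & is.finite(ys)
      bx <- seq(min(xs[ok]), max(xs[ok]), length.out = bins2d + 1L)
      by <- seq(min(ys[ok]), max(ys[ok]), length.out = bins2d + 1L)
      ix <- findInterval(xs[ok], bx, rightmost.closed = TRUE, all.inside = TRUE)
      iy <- findInterval(ys[ok], by, rightmost.closed = TRUE, all.inside = TRUE)
      cm <- matrix(tabulate((iy - 1L) * bins2d + ix, bins2d * bins2d),
                   bins2d, bins2d)
      nz <- which(cm > 0, arr.ind = TRUE)
      grid <- data.frame(xbin = nz[, 1], ybin = nz[, 2], count = cm[nz],
                         r = 0, g = 1, b = 0, alpha = cm[nz] / max(cm))
      joint[[pairName]] <- list(structural = sk, functional = fk,
                                xbreaks = bx, ybreaks = by, bins = grid)
    }
  }
  list(mode = mode, marginal = marginal, joint = joint)
}

#' Connectogram layout data
#'
#' Places the regions on a circle, grouped contiguously by cluster with
#' equal angular spacing 360/r degrees, and lists the chords to draw: the
#' edges with p < alpha_adj, red for t > 0 and blue for t < 0, with
#' opacity mapped affinely from -log10(p) over
#' \[-log10(alpha_adj), max over drawn edges\] to \[0.3, 1\]. Node color
#' saturation is affine in the node's significant-edge degree (0 -> 0.25,
#' max degree -> 1). A run with zero significant edges yields an empty
#' chord list and is valid.
#'
#' @param stats an [EdgeStats-class].
#' @param correction a [CorrectionSpec-class].
#' @param atlas the [RegionAtlas-class].
#' @return list with `nodes` (region, cluster, position, angle_deg,
#'   degree, saturation) and `edges` (region_a, region_b, t, p, color,
#'   opacity).
#' @export
connectogramData <- function(stats, correction, atlas) {
  ids <- regionIds(atlas)
  cl <- regionClusters(atlas)
  r <- nRegions(atlas)
  # contiguous cluster blocks, cluster order = first appearance in atlas
  ord <- order(match(cl, unique(cl)))
  nodes <- data.frame(region_id = ids[ord], cluster = cl[ord],
                      position = seq_len(r),
                      angle_deg = (seq_len(r) - 1) * 360 / r,
                      stringsAsFactors = FALSE)
  tab <- edgeTable(stats)
  sig <- tab[is.finite(tab$p) & tab$p < correction@alphaAdj, , drop = FALSE]
  if (nrow(sig)) {
    nl <- -log10(sig$p)
    lo <- -log10(correction@alphaAdj)
    hi <- max(nl)
    opacity <- if (hi > lo) 0.3 + 0.7 * (nl - lo) / (hi - lo) else rep(1, nrow(sig))
    edges <- data.frame(region_a = sig$region_a, region_b = sig$region_b,
                        t = sig$t, p = sig$p,
                        color = ifelse(sig$t > 0, "red", "blue"),
                        opacity = pmin(opacity, 1),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(region_a = character(), region_b = character(),
                        t = numeric(), p = numeric(),
                        color = character(), opacity = numeric())
  }
  deg <- tabulate(match(c(edges$region_a, edges$region_b), nodes$region_id), r)
  nodes$degree <- deg
  nodes$saturation <- if (max(deg) > 0) 0.25 + 0.75 * deg / max(deg) else rep(0.25, r)
  list(nodes = nodes, edges = edges)
}

#' Matrix (heat map) view of a network or statistic
#'
#' @param x a [ConnectivityNetwork-class] (weights) or an
#'   [EdgeStats-class] (t statistics).
#' @param atlas required for [EdgeStats-class] input.
#' @return symmetric r x r matrix with NA diagonal and NA for masked
#'   edges, region order = atlas order.
#' @export
matrixPlotData <- function(x, atlas = NULL) {
  if (is(x, "ConnectivityNetwork")) {
    m <- netWeights(x)
    diag(m) <- NA_real_
    m
  } else if (is(x, "EdgeStats")) {
    if (is.null(atlas)) stop("atlas required for EdgeStats input")
    index <- buildEdgeIndex(atlas)
    m <- edgeVectorToMatrix(edgeTable(x)$t, index)
    dimnames(m) <- list(regionIds(atlas), regionIds(atlas))
    m
  } else stop("unsupported input")
}
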