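#' Per-edge OLS group-difference statistics
#'
#' Fits, for every edge, an ordinary least squares model
#' `weight ~ intercept + group + covariates` over the subjects with
#' observed data for that edge, and extracts the group coefficient, its t
#' statistic and two-sided p-value. Group is coded 0/1, so positive t means
#' group 1 > group 0. Per-group edge means are computed alongside.
#'
#' Edges with a rank-deficient design (after listwise deletion) are masked
#' with a warning; edges with zero residual variance keep their coefficient
#' but have t and p masked.
#'
#' @param cohort a [ConnectivityCohort-class].
#' @param covariates character vector of covariate column names present in
#'   the subject table (default none).
#' @return an [EdgeStats-class].
#' @export
edgeRegression <- function(cohort, covariates = character()) {
  X <- edgeWeights(cohort)
  subj <- subjectTable(cohort)
  missing_cov <- setdiff(covariates, names(subj))
  if (length(missing_cov))
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  g <- as.numeric(subj$group)
  D <- cbind(`(Intercept)` = 1, group = g)
  for (cv in covariates) D <- cbind(D, as.numeric(subj[[cv]]))
  colnames(D) <- c("(Intercept)", "group", covariates)
  k <- ncol(D)
  M <- nrow(X); n <- ncol(X)

  beta <- tvec <- pvec <- rep(NA_real_, M)
  nUsed <- integer(M); dfree <- rep(NA_real_, M)
  rankWarned <- FALSE

  fitBatch <- function(rows, cols) {
    Ds <- D[cols, , drop = FALSE]
    qrD <- qr(Ds)
    if (qrD$rank < k) {
      if (!rankWarned) {
        warning("rank-deficient design; affected edges masked")
        rankWarned <<- TRUE
      }
      nUsed[rows] <<- length(cols)
      return(invisible())
    }
    if (length(cols) - k < 1L) {
      nUsed[rows] <<- length(cols)
      return(invisible())
    }
    Y <- t(X[rows, cols, drop = FALSE])
    XtXinv <- chol2inv(chol(crossprod(Ds)))
    cf <- XtXinv %*% crossprod(Ds, Y)
    res <- Y - Ds %*% cf
    dfr <- length(cols) - k
    sigma2 <- colSums(res^2) / dfr
    XtXinv_gg <- XtXinv[2L, 2L]
    se <- sqrt(sigma2 * XtXinv_gg)
    b <- cf[2L, ]
    tt <- ifelse(se > 0, b / se, NA_real_)
    pp <- ifelse(is.finite(tt), 2 * pt(-abs(tt), dfr), NA_real_)
    beta[rows] <<- b
    tvec[rows] <<- tt
    pvec[rows] <<- pp
    nUsed[rows] <<- length(cols)
    dfree[rows] <<- dfr
  }

  complete <- !apply(is.na(X), 1L, any)
  if (any(complete)) fitBatch(which(complete), seq_len(n))
  for (e in which(!complete)) {
    cols <- which(!is.na(X[e, ]))
    if (length(cols) <= k || length(unique(g[cols])) < 2L) {
      nUsed[e] <- length(cols)
      next
    }
    fitBatch(e, cols)
  }

  mean0 <- rowMeans(X[, g == 0, drop = FALSE], na.rm = TRUE)
  mean1 <- rowMeans(X[, g == 1, drop = FALSE], na.rm = TRUE)
  mean0[!is.finite(mean0)] <- NA_real_
  mean1[!is.finite(mean1)] <- NA_real_

  rd <- as.data.frame(SummarizedExperiment::rowData(cohort))
  tab <- data.frame(
    edge = rd$edge, region_a = rd$region_a, region_b = rd$region_b,
    cluster_pair = rd$cluster_pair, beta = beta, t = tvec, p = pvec,
    mean0 = mean0, mean1 = mean1, n_used = nUsed, df = dfree,
    stringsAsFactors = FALSE)
  new("EdgeStats", table = tab, kind = networkKind(cohort))
}

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "EdgeStats", function(x) x@table)

#' @rdname networkKind
#' @export
setMethod("networkKind", "EdgeStats", function(x) x@kind)

setMethod("show", "EdgeStats", function(object) {
  tab <- object@table
  cat(sprintf("EdgeStats [%s]: %d edges, %d with finite p (min p = %.3g)\n",
              object@kind, nrow(tab), sum(is.finite(tab$p)),
              suppressWarnings(min(tab$p, na.rm = TRUE))))
})

#' Group mean networks
#'
#' Arithmetic mean of each edge within each group, over non-missing
#' subjects; edges missing for an entire group stay masked.
#'
#' @param cohort a [ConnectivityCohort-class].
#' @return list of two [ConnectivityNetwork-class] objects, `group0` and
#'   `group1`.
#' @export
groupMeanNetworks <- function(cohort) {
  X <- edgeWeights(cohort)
  g <- subjectTable(cohort)$group
  atlas <- cohortAtlas(cohort)
  index <- buildEdgeIndex(atlas)
  one <- function(gv) {
    mu <- rowMeans(X[, g == gv, drop = FALSE], na.rm = TRUE)
    mu[!is.finite(mu)] <- NA_real_
    m <- edgeVectorToMatrix(mu, index)
    diag(m) <- if (networkKind(cohort) %in% c("fMT", "fPC")) 1 else 0
    ConnectivityNetwork(m, networkKind(cohort),
                        paste0("group", gv, "_mean"),
                        regionIds = regionIds(atlas))
  }
  list(group0 = one(0), group1 = one(1))
}

#' Li & Ji eigenvalue rule for the effective number of tests
#'
#' Each eigenvalue lambda of the between-test correlation matrix
#' contributes f(lambda) = 1\[lambda >= 1\] + (lambda - floor(lambda)).
#'
#' @param eigenvalues numeric vector of eigenvalues (small negative values
#'   from roundoff are clipped to 0).
#' @return the effective number of independent tests.
#' @examples
#' mEffFromEigenvalues(c(3, 0, 0))    # 1
#' mEffFromEigenvalues(c(1.5, 0.5))   # 2
#' @export
mEffFromEigenvalues <- function(eigenvalues) {
  lam <- pmax(eigenvalues, 0)
  sum(as.numeric(lam >= 1) + (lam - floor(lam)))
}

#' Effective number of independent edge tests
#'
#' Estimates M_eff for a network kind from the Pearson correlation matrix
#' between edges, computed across pooled subjects of both groups, using the
#' Li & Ji eigenvalue rule ([mEffFromEigenvalues()]). When M_G exceeds the
#' subject count the eigenvalues are obtained from the n x n Gram matrix of
#' the standardized edge rows: the correlation matrix then has at most
#' n - 1 non-zero eigenvalues and the M x M form is never materialized.
#'
#' @param cohort a [ConnectivityCohort-class], or an M x n numeric matrix
#'   of edge weights.
#' @return M_eff, a real in [1, M_G].
#' @export
effectiveNumberOfTests <- function(cohort) {
  X <- if (is(cohort, "ConnectivityCohort")) edgeWeights(cohort) else as.matrix(cohort)
  keep <- !apply(is.na(X), 1L, any)
  X <- X[keep, , drop = FALSE]
  n <- ncol(X); M <- nrow(X)
  if (n < 3L) stop("need at least 3 subjects to estimate M_eff")
  if (M < 1L) stop("no complete edges to estimate M_eff from")
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
  if (any(sdv == 0)) stop("constant edge(s): between-edge correlation undefined")
  Z <- (X - mu) / sdv
  lam <- if (M <= n) {
    eigen(tcrossprod(Z) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  } else {
    eigen(crossprod(Z) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  }
  mEffFromEigenvalues(lam)
}

#' Build a multiple-testing correction record
#'
#' Bonferroni correction with the effective number of independent tests in
#' place of the raw count: alpha_adj = alpha / M_eff. The worm-plot scale
#' s = log10(alpha) / log10(alpha_adj) makes an edge with p = alpha_adj
#' land exactly at height -log10(alpha), so one reference line serves all
#' network kinds.
#'
#' @param mG raw number of edge tests (r(r-1)/2).
#' @param mEff effective number of independent tests, in [1, mG].
#' @param alpha uncorrected significance level (default 0.05).
#' @return a [CorrectionSpec-class].
#' @examples
#' sp <- correctionSpec(mG = 435, mEff = 100)
#' sp@alphaAdj  # 5e-4
#' @export
correctionSpec <- function(mG, mEff, alpha = 0.05) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.finite(mEff) || mEff < 1) stop("mEff must be >= 1")
  alphaAdj <- alpha / mEff
  new("CorrectionSpec", alpha = alpha, mG = as.integer(mG), mEff = mEff,
      alphaAdj = alphaAdj, s = log10(alpha) / log10(alphaAdj))
}

setMethod("show", "CorrectionSpec", function(object) {
  cat(sprintf("CorrectionSpec: alpha=%g, M_G=%d, M_eff=%.2f, alpha_adj=%.3g, s=%.4f\n",
              object@alpha, object@mG, object@mEff, object@alphaAdj, object@s))
})

#' Cluster (lobe-pair) shift tests
#'
#' One-sample two-sided t-test of each cluster-pair's edge t statistics
#' against zero: detects coordinated sub-threshold group differences, i.e.
#' how far each worm is shifted away from t = 0. Clusters with fewer than
#' two finite edge t values, or zero variance, are masked with a warning.
#'
#' @param stats an [EdgeStats-class].
#' @return data.frame with columns `cluster_pair`, `n_edges`, `mean_t`,
#'   `t`, `df`, `p`.
#' @export
clusterShiftTests <- function(stats) {
  tab <- edgeTable(stats)
  sp <- split(tab$t, tab$cluster_pair)
  out <- lapply(names(sp), function(cl) {
    tv <- sp[[cl]][is.finite(sp[[cl]])]
    res <- data.frame(cluster_pair = cl, n_edges = length(tv),
                      mean_t = NA_real_, t = NA_real_,
                      df = NA_real_, p = NA_real_)
    if (length(tv) < 2L || sd(tv) == 0) {
      warning("cluster ", cl, " has <2 usable edges or zero variance; masked")
      if (length(tv)) res$mean_t <- mean(tv)
      return(res)
    }
    tt <- stats::t.test(tv, mu = 0)
    res$mean_t <- mean(tv)
    res$t <- unname(tt$statistic)
    res$df <- unname(tt$parameter)
    res$p <- tt$p.value
    res
  })
  do.call(rbind, out)
}

#' Welch's two-sample t-test from summary statistics
#'
#' Demographic tables usually print only mean, SD and n per group; this
#' computes the Welch statistic, Welch-Satterthwaite degrees of freedom and
#' two-sided p-value directly from those summaries.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return named numeric vector `c(t, df, p)`.
#' @examples
#' welchFromSummary(34.8, 9.8, 23, 38.7, 8.7, 21)["p"]  # ~0.17, prints as 0.2
#' @export
welchFromSummary <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 <= 0 || s2 <= 0) stop("group SDs must be positive")
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  c(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-squared test on a 2 x 2 table
#'
#' @param a,b first row counts; `c`,`d` second row counts (e.g. M/F by
#'   group).
#' @param correct apply Yates continuity correction (default FALSE).
#' @return named numeric vector `c(statistic, df, p)`.
#' @export
chisq2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  tabm <- matrix(counts, 2L, 2L, byrow = TRUE)
  if (any(rowSums(tabm) == 0) || any(colSums(tabm) == 0))
    stop("all table margins must be positive")
  res <- suppressWarnings(stats::chisq.test(tabm, correct = correct))
  c(statistic = unname(res$statistic), df = unname(res$parameter),
    p = res$p.value)
}
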