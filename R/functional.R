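#' Pearson-correlation functional network (fMT)
#'
#' Correlates the mean time series of every region pair. Columns with zero
#' variance cannot be correlated; their edges are masked with a warning
#' rather than failing the whole subject.
#'
#' @param ts T x r numeric matrix of region mean time series (T timepoints,
#'   columns in atlas order; column names taken as region ids).
#' @param subjectId subject identifier.
#' @return a [ConnectivityNetwork-class] of kind `fMT`.
#' @examples
#' ts <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
#' netWeights(pearsonNetwork(ts))[1, 2]  # exactly 1
#' @export
pearsonNetwork <- function(ts, subjectId = "subject") {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 timepoints for correlation")
  sds <- apply(ts, 2L, sd)
  flat <- sds == 0 | !is.finite(sds)
  w <- suppressWarnings(cor(ts))
  w[!is.finite(w)] <- NA_real_
  diag(w) <- 1
  miss <- matrix(FALSE, ncol(ts), ncol(ts))
  if (any(flat)) {
    warning(sum(flat), " zero-variance column(s); their edges are masked")
    miss[flat, ] <- TRUE
    miss[, flat] <- TRUE
    diag(miss) <- FALSE
  }
  ConnectivityNetwork(pmin(pmax(w, -1), 1), "fMT", subjectId,
                      missing = miss, regionIds = colnames(ts))
}

#' Partial-correlation functional network (fPC)
#'
#' Estimates, for every region pair, the correlation of their mean time
#' series with the influence of all other regions removed:
#' r_ij = -p_ij / sqrt(p_ii * p_jj), where p is the inverse of the sample
#' covariance matrix of the region columns (unbiased T-1 denominator).
#'
#' @param ts T x r numeric matrix of region mean time series.
#' @param subjectId subject identifier.
#' @param shrinkage diagonal loading lambda >= 0 added to the covariance
#'   before inversion (default 0, i.e. plain inverse). Useful when T is
#'   barely larger than r.
#' @return a [ConnectivityNetwork-class] of kind `fPC`.
#' @export
partialCorrelationNetwork <- function(ts, subjectId = "subject", shrinkage = 0) {
  ts <- as.matrix(ts)
  r <- ncol(ts)
  if (nrow(ts) < 3L) stop("need at least 3 timepoints")
  S <- cov(ts)
  if (shrinkage > 0) S <- S + diag(shrinkage, r)
  P <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(P)) {
    rk <- qr(S)$rank
    stop("sample covariance is singular (rank ", rk, " of ", r,
         "); need T - 1 >= r and non-degenerate data, or shrinkage > 0")
  }
  P <- (P + t(P)) / 2
  d <- sqrt(diag(P))
  w <- -P / tcrossprod(d)
  diag(w) <- 1
  ConnectivityNetwork(pmin(pmax(w, -1), 1), "fPC", subjectId,
                      regionIds = colnames(ts))
}
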