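## Group-level inference on deconvolved time courses.

## one-sample t statistics per column of a subjects x time matrix
.col_t <- function(mat) {
  n <- nrow(mat)
  m <- colMeans(mat)
  v <- (colSums(mat^2) - n * m^2) / (n - 1)
  m / sqrt(v / n)
}

## maximal run length of TRUE per row of a logical matrix
.max_run <- function(hits) {
  apply(hits, 1L, function(row) {
    r <- rle(row)
    mx <- r$lengths[r$values]
    if (length(mx)) max(mx) else 0L
  })
}

#' Cluster-based permutation test on response time courses
#'
#' One-sample test of a subjects-by-time coefficient matrix against
#' zero, corrected for multiple comparisons over time: time points with
#' a two-tailed t-test `p < alpha` form contiguous clusters scored by
#' their size in samples, and each observed cluster is compared against
#' the permutation distribution of the maximal cluster size under random
#' per-subject sign flips.
#'
#' @param mat Numeric matrix, one row per subject, one column per time
#'   point.
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param alpha Cluster-forming threshold (two-tailed, default 0.05).
#' @param seed Integer seed.
#' @param times Optional time axis (seconds), one per column.
#' @param tail `"two"` (default), `"pos"`, or `"neg"`: which deviations
#'   may form clusters.
#' @return An object of class `cluster_test`: `t_values`, `clusters`
#'   (data frame `start_s`, `end_s`, `start`, `end`, `size`,
#'   `p_corrected`), `alpha`, `n_perm`.
#' @export
cluster_permutation_test <- function(mat, n_perm = 1000, alpha = 0.05,
                                     seed = 1L, times = NULL,
                                     tail = c("two", "pos", "neg")) {
  tail <- match.arg(tail)
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 subjects")
  p <- ncol(mat)
  if (is.null(times)) times <- seq_len(p)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
  tv <- .col_t(mat)
  supra <- switch(tail,
                  two = abs(tv) > tcrit,
                  pos = tv > tcrit,
                  neg = tv < -tcrit)
  r <- rle(as.vector(supra))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  obs <- data.frame(start = starts[r$values], end = ends[r$values])
  obs$size <- obs$end - obs$start + 1L

  # permutation null: sign flips only change column means, the
  # sum-of-squares term is flip-invariant, so all permutations vectorise
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  M <- (signs %*% mat) / n
  ss <- colSums(mat^2)
  V <- sweep(-(n * M^2), 2L, ss, `+`) / (n - 1)
  Tm <- M / sqrt(V / n)
  hits <- switch(tail,
                 two = abs(Tm) > tcrit,
                 pos = Tm > tcrit,
                 neg = Tm < -tcrit)
  null_max <- .max_run(hits)
  obs$p_corrected <- vapply(obs$size, function(sz)
    (1 + sum(null_max >= sz)) / (n_perm + 1), 0.0)
  obs$start_s <- times[obs$start]
  obs$end_s <- times[obs$end]
  structure(list(t_values = tv, times = times,
                 clusters = obs[, c("start_s", "end_s", "start", "end",
                                    "size", "p_corrected")],
                 alpha = alpha, n_perm = n_perm),
            class = "cluster_test")
}

#' @exportS3Method base::print
print.cluster_test <- function(x, ...) {
  sig <- x$clusters[x$clusters$p_corrected < x$alpha, , drop = FALSE]
  cat(sprintf("cluster_test: %d cluster(s), %d significant at alpha = %g (n_perm = %d)\n",
              nrow(x$clusters), nrow(sig), x$alpha, x$n_perm))
  if (nrow(sig)) print(sig, row.names = FALSE)
  invisible(x)
}

#' Interval-summed, sample-normalised coefficients
#'
#' Per subject, sums the coefficient values over a time interval and
#' divides by the number of samples in the interval (i.e. the interval
#' mean). With `alignment = "event_end"` the interval is interpreted
#' relative to the end of the decision interval and lags after the event
#' (post-choice effects) are excluded.
#'
#' @param mat Subjects-by-time coefficient matrix.
#' @param times Time axis in seconds, one per column.
#' @param interval `c(lo, hi)` in seconds.
#' @param alignment `"event_start"` or `"event_end"`.
#' @return One scalar per subject.
#' @export
interval_summary <- function(mat, times, interval,
                             alignment = c("event_start", "event_end")) {
  alignment <- match.arg(alignment)
  mat <- as.matrix(mat)
  sel <- times >= interval[1] & times <= interval[2]
  if (alignment == "event_end") sel <- sel & times <= 0
  if (!any(sel)) stop("interval selects no samples")
  rowSums(mat[, sel, drop = FALSE]) / sum(sel)
}

#' Bootstrapped across-subject regression
#'
#' Regresses a per-subject pupil measure on per-subject model-parameter
#' estimates (all predictors jointly, standardised), resampling subjects
#' with replacement. Confidence bands use the percentile method at 68%
#' coverage; p-values are the two-sided tail fraction of the bootstrap
#' distribution around zero.
#'
#' @param responses Numeric vector, one value per subject.
#' @param predictors Data frame or matrix, one row per subject.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile band (default 0.68).
#' @return An object of class `bootstrap_glm`: `coef` (data frame
#'   `predictor`, `beta`, `ci_lo`, `ci_hi`, `p`), `n_boot`.
#' @export
bootstrap_glm <- function(responses, predictors, n_boot = 10000, seed = 1L,
                          conf = 0.68) {
  X0 <- as.matrix(predictors)
  n <- length(responses)
  stopifnot(nrow(X0) == n)
  sds <- apply(X0, 2, stats::sd)
  if (any(sds == 0)) stop("constant predictor")
  Xs <- scale(X0)
  qx <- qr(cbind(1, Xs))
  if (qx$rank < ncol(Xs) + 1) warning("predictors are collinear")
  fit0 <- qr.coef(qx, responses)[-1]
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, ncol(Xs))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cf <- tryCatch(stats::.lm.fit(cbind(1, Xs[idx, , drop = FALSE]),
                                  responses[idx])$coefficients[-1],
                   error = function(e) rep(NA_real_, ncol(Xs)))
    boots[b, ] <- cf
  }
  lo <- (1 - conf) / 2
  ci <- apply(boots, 2, stats::quantile, probs = c(lo, 1 - lo), na.rm = TRUE)
  pv <- apply(boots, 2, function(v) {
    v <- v[!is.na(v)]
    2 * min(mean(v < 0), mean(v > 0))
  })
  structure(list(coef = data.frame(predictor = colnames(X0) %||%
                                     paste0("x", seq_len(ncol(X0))),
                                   beta = unname(fit0),
                                   ci_lo = unname(ci[1, ]),
                                   ci_hi = unname(ci[2, ]),
                                   p = unname(pv)),
                 n_boot = n_boot),
            class = "bootstrap_glm")
}

#' @exportS3Method base::print
print.bootstrap_glm <- function(x, ...) {
  cat(sprintf("bootstrap_glm (n_boot = %d):\n", x$n_boot))
  print(x$coef, row.names = FALSE)
  invisible(x)
}

#' Scalar amplitude of the biphasic feedback response
#'
#' Peak-to-trough measure: the maximum of the response in the early
#' dilation window minus its minimum in the late constriction window.
#'
#' @param beta Response time course (one subject).
#' @param times Time axis in seconds relative to feedback.
#' @param early Window of the early dilation peak (default 0.5-1.5 s).
#' @param late Window of the late constriction trough (default
#'   1.5-3.0 s).
#' @return Scalar amplitude (non-negative for monotone responses by
#'   construction).
#' @export
feedback_amplitude <- function(beta, times, early = c(0.5, 1.5),
                               late = c(1.5, 3.0)) {
  e <- beta[times >= early[1] & times <= early[2]]
  l <- beta[times >= late[1] & times <= late[2]]
  if (!length(e) || !length(l)) stop("amplitude windows outside the estimate")
  max(e) - min(l)
}
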