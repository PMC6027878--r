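#' Robust multivariate outlier screen (MCD)
#'
#' Screens specimens within each genotype-by-stage group using the
#' Minimum Covariance Determinant estimator: robust location and scatter
#' are estimated on the determinant-minimizing data subset, so undetected
#' outliers cannot inflate the covariance used to judge them. Each
#' specimen's robust Mahalanobis distance from the robust mean is
#' converted to SD units as a robust z-score of the group's distance
#' distribution, `(d - median(d)) / mad(d)`; specimens are flagged at 3
#' (putative outlier, to be re-examined) and 6 SD (candidate for
#' omission). Flagged specimens are reported, never dropped: the
#' keep/drop decision is an explicit exclusion list downstream.
#'
#' Screening is performed on the first `n_axes` (default 5) columns of
#' the pooled shape PC scores, subset within each group.
#'
#' @param scores n x q matrix of pooled shape PC scores (q >= `n_axes`).
#' @param groups group label per specimen (e.g. `stage/genotype`
#'   interaction).
#' @param ids specimen ids; defaults to rownames of `scores`.
#' @param n_axes number of leading axes screened (default 5).
#' @param support_fraction fraction of observations whose covariance
#'   determinant is minimized; default the maximal-breakdown choice
#'   `ceiling((n + p + 1) / 2) / n`.
#' @param nsamp subsets sampled by the MCD search (passed to
#'   [MASS::cov.rob()]).
#' @param units `"robust_z"` (default, the SD units described above),
#'   `"distance"` (raw robust Mahalanobis distance), or `"chisq"`
#'   (sqrt of the chi-squared quantile-equivalent of the distance). Flag
#'   thresholds 3/6 always apply to the reported `robust_distance_sd`.
#' @return data.frame of class `outlier_report`: `id`, `group`,
#'   `robust_distance` (raw), `robust_distance_sd` (in the chosen
#'   units), `flag` (`none`/`over3sd`/`over6sd`), `decision` (all
#'   `"review"` or `"keep"`; user-controlled downstream). Groups too
#'   small to screen (n <= n_axes + 1) or with singular robust scatter
#'   are skipped with a warning and get `NA` distances.
#' @export
mcd_screen <- function(scores, groups, ids = NULL, n_axes = 5L,
                       support_fraction = NULL, nsamp = 500L,
                       units = c("robust_z", "distance", "chisq")) {
  units <- match.arg(units)
  scores <- as.matrix(scores)
  if (ncol(scores) < n_axes)
    stop("scores have ", ncol(scores), " axes; need ", n_axes)
  X <- scores[, seq_len(n_axes), drop = FALSE]
  if (is.null(ids)) ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  groups <- as.character(groups)
  out <- data.frame(id = ids, group = groups,
                    robust_distance = NA_real_,
                    robust_distance_sd = NA_real_,
                    flag = "none", decision = "keep",
                    stringsAsFactors = FALSE)
  for (grp in unique(groups)) {
    ix <- which(groups == grp)
    n <- length(ix)
    if (n <= n_axes + 1L) {
      warning("group '", grp, "' too small to screen (n = ", n,
              ", axes = ", n_axes, "); skipped")
      next
    }
    Xi <- X[ix, , drop = FALSE]
    h <- if (is.null(support_fraction)) ceiling((n + n_axes + 1) / 2)
    else ceiling(support_fraction * n)
    fit <- tryCatch(
      MASS::cov.rob(Xi, method = "mcd", quantile.used = h, nsamp = nsamp),
      error = function(e) NULL)
    if (is.null(fit) ||
        inherits(tryCatch(chol(fit$cov), error = function(e) e,
                          silent = TRUE), "error")) {
      warning("singular robust scatter in group '", grp, "'; skipped")
      next
    }
    d <- sqrt(stats::mahalanobis(Xi, fit$center, fit$cov))
    z <- switch(units,
      robust_z = (d - stats::median(d)) / stats::mad(d),
      distance = d,
      chisq = sqrt(stats::qchisq(
        pmin(stats::pchisq(d^2, df = n_axes), 1 - 1e-15), df = 1)))
    out$robust_distance[ix] <- d
    out$robust_distance_sd[ix] <- z
    out$flag[ix] <- ifelse(z > 6, "over6sd",
                           ifelse(z > 3, "over3sd", "none"))
    out$decision[ix] <- ifelse(z > 3, "review", "keep")
  }
  class(out) <- c("outlier_report", class(out))
  out
}

#' Grubbs' test for a single univariate outlier
#'
#' Two-sided Grubbs statistic G = max|x - mean| / sd compared with the
#' exact critical value from the t-distribution,
#' G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)) with
#' t = qt(1 - alpha/(2n), n - 2). Used to screen size measures (areas,
#' centroid size); at most one index is flagged per call.
#'
#' @param values finite numeric vector, length >= 3, non-constant.
#' @param alpha significance level (default 0.05).
#' @return list: `index` (integer of the flagged value, or `integer(0)`
#'   if none), `G`, `critical`.
#' @export
grubbs_screen <- function(values, alpha = 0.05) {
  stopifnot(length(values) >= 3, all(is.finite(values)))
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: Grubbs' test undefined")
  n <- length(values)
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tq <- stats::qt(1 - alpha / (2 * n), n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  list(index = if (G > crit) which.max(dev) else integer(0),
       G = G, critical = crit)
}
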