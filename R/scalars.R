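#' Standardize a configuration by centroid size
#'
#' Divides every coordinate by the configuration's centroid size, so the
#' result has unit centroid size and all scalars derived from it are
#' dimensionless and invariant to uniform scaling. Idempotent.
#'
#' @param m p x 2 matrix.
#' @return p x 2 matrix with centroid size 1.
#' @export
standardize_config <- function(m) m / centroid_size(m)

#' Pairwise standardized distances between the 8 fixed landmarks
#'
#' Euclidean distance for each of the 28 unordered pairs (i, j),
#' 1 <= i < j <= 8, of a centroid-size-standardized configuration. Named
#' `stlen12` ... `stlen78`.
#'
#' @param m p x 2 matrix, already standardized (see
#'   [standardize_config()]).
#' @param n_fixed number of fixed landmarks (8).
#' @return named numeric vector of length `choose(n_fixed, 2)`.
#' @export
pairwise_distances <- function(m, n_fixed = 8L) {
  stopifnot(nrow(m) >= n_fixed)
  pr <- utils::combn(n_fixed, 2L)
  d <- sqrt(rowSums((m[pr[1L, ], , drop = FALSE] -
                       m[pr[2L, ], , drop = FALSE])^2))
  names(d) <- paste0("stlen", pr[1L, ], pr[2L, ])
  d
}

# ordered vertex paths for margins and area polygons
margin_path <- function(which) switch(which,
  anterior  = c(1L, 9:14, 3L),
  posterior = c(5L, 15:17, 7L),
  stop("unknown margin '", which, "'"))

area_path <- function(which) switch(which,
  anterior  = c(2L, 1L, 9:14, 3L, 4L),
  middle    = c(4L, 3L, 5L, 6L),
  posterior = c(6L, 5L, 15:17, 7L, 8L),
  total     = c(2L, 1L, 9:14, 3L, 5L, 15:17, 7L, 8L, 6L),
  stop("unknown area region '", which, "'"))

#' Margin polyline length
#'
#' Length of the polyline along the anterior margin (landmarks 1 and 3
#' with semilandmarks 9-14 between) or the posterior margin (landmarks 5
#' and 7 with semilandmarks 15-17 between), on a standardized
#' configuration.
#'
#' @param m p x 2 matrix (standardized for the dimensionless measure).
#' @param which `"anterior"` or `"posterior"`.
#' @return positive scalar.
#' @export
margin_length <- function(m, which = c("anterior", "posterior")) {
  which <- match.arg(which)
  v <- m[margin_path(which), , drop = FALSE]
  sum(sqrt(rowSums(diff(v)^2)))
}

# do segments p1-p2 and p3-p4 properly intersect?
segs_intersect <- function(p1, p2, p3, p4) {
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

is_simple_polygon <- function(v) {
  k <- nrow(v)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i + 1L || (i == 1L && j == k)) next
    if (segs_intersect(v[i, ], v[i %% k + 1L, ],
                       v[j, ], v[j %% k + 1L, ])) return(FALSE)
  }
  TRUE
}

# surveyor's (shoelace) formula, signed
shoelace_signed <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  sum(x * (y[c(2:length(y), 1)] - y[c(length(y), 1:(length(y) - 1))])) / 2
}

#' Polygon area of a wing region (surveyor's formula)
#'
#' Absolute shoelace area over the documented vertex ordering:
#' anterior 2,1,9-14,3,4; middle 4,3,5,6; posterior 6,5,15-17,7,8;
#' total 2,1,9-14,3,5,15-17,7,8,6 (the 3-5 gap bridged by the chord).
#' On raw coordinates the result is in mm^2; on a standardized
#' configuration it is a dimensionless shape measure. A warning with the
#' signed area is issued if the vertex path self-intersects.
#'
#' @param m p x 2 matrix (17 landmarks).
#' @param which `"anterior"`, `"middle"`, `"posterior"` or `"total"`.
#' @param vertices optional explicit vertex index path overriding
#'   `which`.
#' @param check test the vertex path for self-intersection (set `FALSE`
#'   to skip the O(k^2) check in tight loops).
#' @return positive scalar.
#' @export
polygon_area <- function(m, which = c("total", "anterior", "middle",
                                      "posterior"),
                         vertices = NULL, check = TRUE) {
  if (is.null(vertices)) vertices <- area_path(match.arg(which))
  v <- m[vertices, , drop = FALSE]
  a <- shoelace_signed(v)
  if (check && !is_simple_polygon(v))
    warning("self-intersecting polygon (signed area ", signif(a, 6),
            "); result may not be a region area")
  abs(a)
}

#' Per-specimen scalar trait table
#'
#' Computes, for every specimen of a [wing_set()] (raw coordinates, mm):
#' the 28 standardized pairwise landmark distances, the two standardized
#' margin lengths, the four polygon areas in mm^2 and their standardized
#' (dimensionless) variants, and centroid size (mm). Standardized
#' quantities are invariant to rotation, translation and uniform scaling
#' of the raw configuration.
#'
#' @param x a [wing_set()].
#' @return data.frame: metadata columns, `stlen..` x 28,
#'   `anterior_margin_len`, `posterior_margin_len`,
#'   `area_{anterior,middle,posterior,total}` (mm^2),
#'   `std_area_*` (dimensionless), `centroid_size` (mm).
#' @export
scalar_table <- function(x) {
  stopifnot(inherits(x, "wing_set"))
  n <- n_specimens(x)
  regions <- c("anterior", "middle", "posterior", "total")
  rows <- vector("list", n)
  nonsimple <- character()
  for (i in seq_len(n)) {
    m <- x$coords[, , i]
    s <- standardize_config(m)
    d <- pairwise_distances(s)
    if (!is_simple_polygon(m[area_path("total"), , drop = FALSE]))
      nonsimple <- c(nonsimple, x$info$id[i])
    areas <- vapply(regions, function(w) polygon_area(m, w, check = FALSE),
                    0)
    std_areas <- vapply(regions, function(w)
      polygon_area(s, w, check = FALSE), 0)
    rows[[i]] <- c(d,
                   anterior_margin_len = margin_length(s, "anterior"),
                   posterior_margin_len = margin_length(s, "posterior"),
                   stats::setNames(areas, paste0("area_", regions)),
                   stats::setNames(std_areas, paste0("std_area_", regions)),
                   centroid_size = centroid_size(m))
  }
  if (length(nonsimple))
    warning(length(nonsimple),
            " specimen(s) with self-intersecting total outline: ",
            paste(utils::head(nonsimple, 5), collapse = ", "),
            if (length(nonsimple) > 5) ", ...")
  cbind(x$info, as.data.frame(do.call(rbind, rows)))
}

#' Bootstrap ratio of group means
#'
#' Point estimate: mean(numerator group) / mean(denominator group). For
#' each of `n_boot` replicates, BOTH groups are independently resampled
#' with replacement at their own sizes and the ratio of resampled means
#' recorded, giving a bootstrap distribution and a 2.5-97.5 percentile
#' confidence interval. Replicates whose denominator mean is exactly zero
#' are redrawn (warned about if they exceed 1%).
#'
#' @param values_num,values_den numeric vectors (non-empty; denominator
#'   mean bounded away from zero).
#' @param n_boot bootstrap replicates (study convention: 1000).
#' @param seed RNG seed.
#' @return list of class `ratio_comparison`: `point_ratio`, `boot`
#'   (length `n_boot`), `ci` (2.5% and 97.5% percentiles), `se_boot`,
#'   `n_num`, `n_den`, `n_redrawn`.
#' @export
bootstrap_ratio <- function(values_num, values_den, n_boot = 1000L,
                            seed = NULL) {
  stopifnot(length(values_num) >= 1, length(values_den) >= 1, n_boot >= 1)
  if (mean(values_den) == 0) stop("denominator group mean is zero")
  n1 <- length(values_num); n2 <- length(values_den)
  point <- mean(values_num) / mean(values_den)
  redrawn <- 0L
  boot <- with_seed(seed, function() {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        md <- mean(values_den[sample.int(n2, n2, replace = TRUE)])
        if (md != 0) break
        redrawn <<- redrawn + 1L
      }
      mean(values_num[sample.int(n1, n1, replace = TRUE)]) / md
    }, 0)
  })
  if (redrawn > 0.01 * n_boot)
    warning(redrawn, " bootstrap replicates redrawn for zero denominator")
  structure(list(point_ratio = point, boot = boot,
                 ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
                 se_boot = stats::sd(boot),
                 n_num = n1, n_den = n2, n_redrawn = redrawn),
            class = "ratio_comparison")
}

#' @export
print.ratio_comparison <- function(x, ...) {
  cat(sprintf("ratio of means: %.4g (95%% bootstrap CI %.4g-%.4g, %d reps)\n",
              x$point_ratio, x$ci[1], x$ci[2], length(x$boot)))
  invisible(x)
}

#' Delta-method standard error of a ratio of means
#'
#' SE(a/b) = |a/b| * sqrt((se_a/a)^2 + (se_b/b)^2), assuming zero
#' covariance between numerator and denominator (groups are independent:
#' specimens are destructively sampled per stage), which makes the SE
#' conservative.
#'
#' @param mean_a,se_a numerator mean and its SE.
#' @param mean_b,se_b denominator mean and its SE (`mean_b` nonzero).
#' @return non-negative scalar.
#' @export
ratio_se_delta <- function(mean_a, se_a, mean_b, se_b) {
  stopifnot(se_a >= 0, se_b >= 0)
  if (mean_b == 0) stop("denominator mean is zero")
  abs(mean_a / mean_b) * sqrt((se_a / mean_a)^2 + (se_b / mean_b)^2)
}

#' Normal-approximation test for a difference between two ratios
#'
#' @param ratio1,se1,ratio2,se2 two independent ratio estimates with
#'   their (delta-method) SEs.
#' @return list: `diff`, `se`, `z`, `p_value` (two-sided).
#' @export
ratio_diff_test <- function(ratio1, se1, ratio2, se2) {
  se <- sqrt(se1^2 + se2^2)
  z <- (ratio1 - ratio2) / se
  list(diff = ratio1 - ratio2, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Factorial fixed-effects model for a scalar trait
#'
#' Fits trait ~ stage * genotype * sex (all supplied factors, fully
#' crossed) with Type III (marginal) F tests under sum-to-zero
#' contrasts. Interaction terms with P > `drop_p` (default 0.2) are
#' dropped, highest order first, and the model refit. Pairwise genotype
#' comparisons on the least-squares means are adjusted with the
#' Tukey-Kramer method. Areas should be supplied log10-transformed
#' (`log10_transform = TRUE`).
#'
#' @param values numeric trait vector.
#' @param factors data.frame of factors (e.g. stage, genotype, sex).
#' @param log10_transform apply log10 to `values` first.
#' @param drop_p interaction removal threshold.
#' @return list of class `factorial_fit`: `anova` (data.frame of Type
#'   III F tests for the final model), `dropped` (character),
#'   `tukey` (data.frame of pairwise genotype comparisons, when a
#'   `genotype` factor is present), `model` (the `lm` fit).
#' @export
fit_factorial <- function(values, factors, log10_transform = FALSE,
                          drop_p = 0.2) {
  factors <- as.data.frame(factors)
  factors[] <- lapply(factors, factor)
  if (log10_transform) {
    stopifnot(all(values > 0))
    values <- log10(values)
  }
  dat <- cbind(y = values, factors)
  terms_now <- attr(stats::terms(stats::as.formula(
    paste("~", paste(names(factors), collapse = "*")))), "term.labels")
  type3 <- function(terms_use) {
    fml <- stats::as.formula(paste("y ~", paste(terms_use, collapse = "+")))
    X <- stats::model.matrix(fml, dat,
                             contrasts.arg = lapply(factors, function(.)
                               "contr.sum"))
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient design (aliased terms): ",
           paste(terms_use, collapse = ", "))
    fit <- stats::lm(fml, dat,
                     contrasts = lapply(factors, function(.) "contr.sum"))
    asgn <- attr(X, "assign")
    rss_full <- sum(stats::resid(fit)^2)
    df_res <- fit$df.residual
    tab <- do.call(rbind, lapply(seq_along(terms_use), function(t) {
      Xr <- X[, asgn != t, drop = FALSE]
      rss_red <- sum(stats::resid(stats::lm.fit(Xr, values))^2)
      q <- sum(asgn == t)
      Fv <- ((rss_red - rss_full) / q) / (rss_full / df_res)
      data.frame(term = terms_use[t], df = q,
                 sum_sq = rss_red - rss_full, F = Fv,
                 p_value = stats::pf(Fv, q, df_res, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
    list(fit = fit, tab = tab, df_res = df_res)
  }
  dropped <- character()
  repeat {
    res <- type3(terms_now)
    inter <- grepl(":", res$tab$term)
    # drop the least significant removable (highest-order) interaction
    ord <- lengths(regmatches(res$tab$term, gregexpr(":", res$tab$term)))
    removable <- inter & ord == max(c(0, ord[inter])) &
      res$tab$p_value > drop_p
    if (!any(removable)) break
    worst <- res$tab$term[removable][which.max(res$tab$p_value[removable])]
    dropped <- c(dropped, worst)
    terms_now <- setdiff(terms_now, worst)
  }
  tukey <- NULL
  if ("genotype" %in% names(factors) && nlevels(factors$genotype) >= 2) {
    fit <- res$fit
    lev <- levels(factors$genotype)
    # LS-means: predictions averaged over the factorial grid
    grid <- expand.grid(lapply(factors, levels))
    lsm <- vapply(lev, function(gl) {
      g2 <- grid; g2$genotype <- factor(gl, levels = lev)
      mean(stats::predict(fit, newdata = unique(g2)))
    }, 0)
    # SE of LS-mean differences via the prediction design
    Xg <- lapply(lev, function(gl) {
      g2 <- unique({g <- grid; g$genotype <- factor(gl, levels = lev); g})
      colMeans(stats::model.matrix(stats::delete.response(stats::terms(fit)),
                                   g2, contrasts.arg = fit$contrasts))
    })
    V <- stats::vcov(fit)
    cmp <- utils::combn(length(lev), 2)
    tukey <- do.call(rbind, lapply(seq_len(ncol(cmp)), function(k) {
      a <- cmp[1, k]; b <- cmp[2, k]
      ct <- Xg[[a]] - Xg[[b]]
      se <- sqrt(drop(t(ct) %*% V %*% ct))
      diff <- lsm[a] - lsm[b]
      q <- abs(diff) / (se / sqrt(2))
      data.frame(comparison = paste(lev[a], lev[b], sep = " - "),
                 estimate = diff, se = se,
                 p_adj = stats::ptukey(q, length(lev), res$df_res,
                                       lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(anova = res$tab, dropped = dropped, tukey = tukey,
                 model = res$fit),
            class = "factorial_fit")
}
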