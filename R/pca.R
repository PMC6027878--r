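#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance of the registered shape
#' coordinates. Axes are ordered by decreasing eigenvalue; each axis is
#' signed so its largest-magnitude loading is positive. After Procrustes
#' registration and sliding the covariance is rank-deficient (similarity
#' parameters and sliding constraints are removed), so `n_axes` is
#' truncated to the numerical rank with a warning when it exceeds it.
#'
#' @param g a `wing_gpa` from [gpa()], or an n x 2p shape matrix.
#' @param n_axes number of axes to retain (default 18, the number used
#'   for all downstream multivariate analyses).
#' @return list of class `shape_pca`: `scores` (n x n_axes), `loadings`
#'   (2p x n_axes), `eigenvalues` (all, length 2p), `center`, `rank`.
#' @export
shape_pca <- function(g, n_axes = 18L) {
  Y <- if (inherits(g, "wing_gpa")) g$shapes else as.matrix(g)
  n <- nrow(Y)
  if (n <= n_axes)
    stop("need more specimens (", n, ") than retained axes (", n_axes, ")")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  sv <- svd(Yc)
  ev <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_axes > rank) {
    warning("n_axes (", n_axes, ") exceeds rank (", rank,
            "); truncating")
    n_axes <- rank
  }
  load <- sv$v[, seq_len(n_axes), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(n_axes)) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  scores <- Yc %*% load
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(n_axes))
  rownames(scores) <- rownames(Y)
  structure(list(scores = scores, loadings = load,
                 eigenvalues = ev, center = ctr, rank = rank),
            class = "shape_pca")
}

#' Canonical variate (discriminant) analysis
#'
#' Finds the linear combinations of the input variables (typically
#' retained shape PCs) that maximize between-class relative to
#' within-class scatter. Scores are sphered so the pooled within-class
#' covariance of the canonical scores is the identity.
#'
#' @param scores n x q numeric matrix.
#' @param labels class labels, length n; at least 2 classes with at
#'   least 2 members each.
#' @return list of class `wing_cva`: `scores` (n x m canonical scores,
#'   m = min(classes - 1, q)), `vectors` (q x m), `eigenvalues`,
#'   `labels`.
#' @export
cva <- function(scores, labels) {
  X <- as.matrix(scores)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("every class needs at least 2 members")
  n <- nrow(X); q <- ncol(X); k <- nlevels(labels)
  grand <- colMeans(X)
  W <- matrix(0, q, q); B <- matrix(0, q, q)
  for (lv in levels(labels)) {
    Xi <- X[labels == lv, , drop = FALSE]
    mi <- colMeans(Xi)
    Ci <- sweep(Xi, 2, mi)
    W <- W + crossprod(Ci)
    B <- B + nrow(Xi) * tcrossprod(mi - grand)
  }
  W <- W / (n - k)
  eW <- eigen(W, symmetric = TRUE)
  if (min(eW$values) < max(eW$values) * 1e-10)
    stop("singular within-class scatter; retain fewer PCs")
  Whalf <- eW$vectors %*% diag(1 / sqrt(eW$values), q) %*% t(eW$vectors)
  M <- Whalf %*% B %*% Whalf / (n - k)
  eM <- eigen(M, symmetric = TRUE)
  m <- min(k - 1L, q)
  vec <- Whalf %*% eM$vectors[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    kk <- which.max(abs(vec[, j]))
    if (vec[kk, j] < 0) vec[, j] <- -vec[, j]
  }
  sc <- sweep(X, 2, grand) %*% vec
  colnames(sc) <- colnames(vec) <- paste0("CV", seq_len(m))
  structure(list(scores = sc, vectors = vec,
                 eigenvalues = pmax(eM$values[seq_len(m)], 0),
                 labels = labels),
            class = "wing_cva")
}
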