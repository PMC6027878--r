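#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid: the standard geometric-morphometrics size measure,
#' invariant to rotation and translation and linear in uniform scaling.
#' For these wings it is proportional to the square root of wing area.
#'
#' @param m p x 2 numeric matrix.
#' @return positive scalar.
#' @export
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # sqrt(2)
centroid_size <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 2, nrow(m) >= 2)
  cs <- sqrt(sum(sweep(m, 2, colMeans(m))^2))
  if (cs == 0) stop("degenerate configuration: all points coincident")
  cs
}

as_complex <- function(m) complex(real = m[, 1], imaginary = m[, 2])
as_matrix2 <- function(z) cbind(x = Re(z), y = Im(z))

# center and scale to unit centroid size (complex vector)
center_unit <- function(z) {
  z <- z - mean(z)
  s <- sqrt(sum(Mod(z)^2))
  if (s == 0) stop("degenerate configuration: all points coincident")
  z / s
}

# rotate z (centered) onto w (centered) by rotation-only least squares;
# reflections are never used (all wings share handedness)
rotate_onto <- function(z, w) {
  s <- sum(w * Conj(z))
  if (Mod(s) == 0) return(z)  # rotation undetermined; leave as is
  z * s / Mod(s)
}

#' Procrustes distance between two configurations
#'
#' Minimized root-sum-of-squares between the two shapes after centering,
#' scaling to unit centroid size and optimal rotation (rotation only: the
#' reflection is excluded). Zero iff the shapes are similarity-equivalent.
#'
#' @param a,b p x 2 matrices over the same scheme.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  z <- center_unit(as_complex(a))
  w <- center_unit(as_complex(b))
  sqrt(max(0, 2 - 2 * Mod(sum(w * Conj(z)))))
}

# rotate configurations (complex n-list or matrix) so the principal axis
# of the consensus lies along x, with a deterministic 180-degree fix
principal_axis_rotation <- function(cons) {
  v <- eigen(stats::cov(as_matrix2(cons)), symmetric = TRUE)$vectors[, 1]
  theta <- -atan2(v[2], v[1])
  rot <- complex(argument = theta)
  c1 <- cons[1] * rot
  if (Re(c1) > 0 || (Re(c1) == 0 && Im(c1) > 0)) rot <- -rot
  rot
}

#' Generalized Procrustes alignment
#'
#' Jointly superimposes all specimens (all stages and genotypes
#' together): each configuration is centered, scaled to unit centroid
#' size and rotated to the running consensus by rotation-only least
#' squares; the consensus is the mean of the rotated shapes, renormalized
#' to unit centroid size; iteration stops when the consensus moves by
#' less than `tol`. The output orientation is fixed by rotating the
#' consensus principal axis onto the x axis (with a deterministic sign
#' rule), so results are reproducible across runs and input orderings.
#'
#' @param x a [wing_set()] or a p x 2 x n array.
#' @param max_iter,tol iteration control on consensus change (Euclidean
#'   norm of the consensus coordinate vector).
#' @return object of class `wing_gpa`: list with `coords` (p x 2 x n
#'   aligned, unit centroid size), `shapes` (n x 2p row-vector form),
#'   `consensus` (p x 2, unit centroid size), `centroid_sizes` (mm),
#'   `info`, `scheme`, `iterations`, `converged`, `slid`.
#' @export
gpa <- function(x, max_iter = 100L, tol = 1e-10) {
  if (inherits(x, "wing_set")) {
    coords <- x$coords; info <- x$info; scheme <- x$scheme
  } else {
    coords <- x; info <- NULL; scheme <- NULL
  }
  n <- dim(coords)[3]
  if (is.na(n) || n < 2) stop("need at least 2 specimens")
  zs <- lapply(seq_len(n), function(i) as_complex(coords[, , i]))
  sizes <- vapply(zs, function(z) sqrt(sum(Mod(z - mean(z))^2)), 0)
  zs <- lapply(zs, center_unit)
  cons <- zs[[1]]
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    zs <- lapply(zs, rotate_onto, w = cons)
    new_cons <- Reduce(`+`, zs) / n
    new_cons <- center_unit(new_cons)
    delta <- sqrt(sum(Mod(new_cons - cons)^2))
    cons <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  rot <- principal_axis_rotation(cons)
  cons <- cons * rot
  zs <- lapply(zs, function(z) rotate_onto(z * rot, cons))
  arr <- array(NA_real_, dim(coords))
  for (i in seq_len(n)) arr[, , i] <- as_matrix2(zs[[i]])
  dimnames(arr) <- dimnames(coords)
  res <- list(coords = arr, shapes = flatten_shapes(arr),
              consensus = as_matrix2(cons), centroid_sizes = sizes,
              info = info, scheme = scheme, iterations = iter,
              converged = converged, slid = FALSE)
  if (!is.null(info)) rownames(res$shapes) <- info$id
  class(res) <- "wing_gpa"
  res
}

#' @export
print.wing_gpa <- function(x, ...) {
  cat("wing_gpa:", dim(x$coords)[3], "aligned specimens,",
      dim(x$coords)[1], "landmarks;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations;",
      if (x$slid) "semilandmarks slid" else "no sliding", "\n")
  invisible(x)
}

# total Procrustes sum of squares around the consensus
procrustes_ss <- function(g) {
  sum((g$shapes - matrix(as.vector(t(g$consensus)),
                         nrow(g$shapes), ncol(g$shapes), byrow = TRUE))^2)
}

#' Slide semilandmarks along the margin
#'
#' Chord-tangent (perpendicular projection) sliding against Procrustes
#' distance: each semilandmark is moved along its local tangent -- the
#' chord between its flanking points in the ordered margin sequence
#' (anchors included) -- to the foot of the perpendicular from the
#' corresponding consensus point. Sliding alternates with Procrustes
#' re-registration until the total Procrustes sum of squares decreases by
#' less than `tol`; an iteration that would increase it is rolled back,
#' so the objective is non-increasing by construction.
#'
#' @param g a `wing_gpa` from [gpa()].
#' @param scheme a [wing_scheme()]; defaults to the one stored in `g`.
#' @param mode `"chord"` (default) or `"none"` (return `g` unchanged).
#' @param max_iter,tol outer iteration control on the Procrustes SS. The
#'   default caps sliding at 10 alternations: with heterogeneous groups
#'   the consensus keeps moving slightly and unbounded sliding would let
#'   semilandmarks creep along the margin, absorbing real between-group
#'   signal.
#' @return a `wing_gpa` with slid, re-registered coordinates
#'   (`slid = TRUE`) and `slide_ss`, the SS trace across iterations.
#' @export
slide_semilandmarks <- function(g, scheme = g$scheme,
                                mode = c("chord", "none"),
                                max_iter = 10L, tol = 1e-10) {
  mode <- match.arg(mode)
  if (mode == "none") return(g)
  if (is.null(scheme)) stop("no landmark scheme available for sliding")
  n <- dim(g$coords)[3]
  arr <- g$coords
  cons <- g$consensus
  ss <- procrustes_ss(g)
  trace <- ss
  state <- g
  for (it in seq_len(max_iter)) {
    new_arr <- arr
    for (grp_name in names(scheme$semi_groups)) {
      grp <- scheme$semi_groups[[grp_name]]
      seqn <- c(grp$anchor_start, grp$semis, grp$anchor_end)
      for (i in seq_len(n)) {
        pts <- arr[seqn, , i]
        for (k in seq_along(grp$semis)) {
          prev <- pts[k, ]; nxt <- pts[k + 2L, ]
          tv <- nxt - prev
          tn <- sqrt(sum(tv^2))
          if (tn < 1e-12)
            stop("degenerate tangent for specimen ",
                 if (!is.null(g$info)) g$info$id[i] else i,
                 " in semilandmark group '", grp_name, "'")
          tv <- tv / tn
          j <- grp$semis[k]
          p <- arr[j, , i]
          cj <- cons[j, ]
          new_arr[j, , i] <- p + sum((cj - p) * tv) * tv
        }
      }
    }
    # re-register the slid configurations
    reg <- gpa(new_arr, max_iter = 100L, tol = 1e-10)
    new_ss <- procrustes_ss(reg)
    if (new_ss > ss + 1e-15) break     # roll back: keep previous state
    improved <- ss - new_ss
    arr <- reg$coords
    cons <- reg$consensus
    state <- reg
    ss <- new_ss
    trace <- c(trace, ss)
    if (improved < tol) break
  }
  state$centroid_sizes <- g$centroid_sizes
  state$info <- g$info
  state$scheme <- scheme
  if (!is.null(state$info)) {
    dimnames(state$coords)[[3]] <- state$info$id
    rownames(state$shapes) <- state$info$id
  }
  state$slid <- TRUE
  state$slide_ss <- trace
  state
}

#' Ordinary Procrustes alignment of one configuration onto a target
#'
#' Centers and scales `m` to unit centroid size, then rotates it
#' (rotation only) onto the centered, unit-scaled `target`. Useful for
#' expressing an external reference shape (e.g. a generator template) in
#' the coordinate frame of a GPA consensus.
#'
#' @param m,target p x 2 matrices.
#' @return p x 2 matrix: `m` aligned onto the normalized target.
#' @export
opa_align <- function(m, target) {
  z <- center_unit(as_complex(m))
  w <- center_unit(as_complex(target))
  as_matrix2(rotate_onto(z, w))
}

#' Tangent-space adequacy check
#'
#' Pearson correlation between all-pairs Euclidean distances of the
#' registered coordinates and all-pairs Procrustes distances. Values near
#' 1 indicate the linear tangent-space approximation is adequate for the
#' observed range of shapes.
#'
#' @param g a `wing_gpa`.
#' @return correlation in \[-1, 1\].
#' @export
tangent_check <- function(g) {
  n <- dim(g$coords)[3]
  if (n < 3) stop("need at least 3 specimens")
  eu <- as.vector(stats::dist(g$shapes))
  pr <- numeric(length(eu))
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    k <- k + 1L
    pr[k] <- procrustes_distance(g$coords[, , i], g$coords[, , j])
  }
  stats::cor(eu, pr)
}
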