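#' Mean shape-distance matrix among stage/genotype groups
#'
#' Mean Euclidean distance in shape space (centroid-size units) between
#' the registered 2p-element shape vectors of individuals, for every pair
#' of stage/genotype groups. Diagonal entries are the average distances
#' between *different* individuals of the same group (self-pairs
#' excluded); groups of size 1 get an `NA` diagonal.
#'
#' @param g a `wing_gpa`, or an n x 2p shape matrix.
#' @param stage,genotype group labels; default taken from `g$info`.
#' @return symmetric numeric matrix with `stage/genotype` dimnames,
#'   groups ordered stage-major.
#' @export
mean_shape_distance_matrix <- function(g, stage = NULL, genotype = NULL) {
  Y <- if (inherits(g, "wing_gpa")) g$shapes else as.matrix(g)
  if (is.null(stage)) stage <- g$info$stage
  if (is.null(genotype)) genotype <- g$info$genotype
  stage <- factor(stage, levels = intersect(STAGES, unique(stage)))
  genotype <- factor(genotype,
                     levels = union(intersect(GENOTYPES, unique(genotype)),
                                    unique(genotype)))
  key <- interaction(stage, genotype, sep = "/", lex.order = TRUE,
                     drop = TRUE)
  lev <- levels(key)
  D <- as.matrix(stats::dist(Y))
  out <- matrix(NA_real_, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (a in seq_along(lev)) for (b in seq(a, length(lev))) {
    ia <- which(key == lev[a]); ib <- which(key == lev[b])
    if (a == b) {
      if (length(ia) >= 2) {
        sub <- D[ia, ia, drop = FALSE]
        out[a, a] <- mean(sub[upper.tri(sub)])
      }
    } else {
      out[a, b] <- out[b, a] <- mean(D[ia, ib])
    }
  }
  out
}

#' Angles between genotype shape-change trajectories
#'
#' For each developmental transition, the average direction of shape
#' change of a genotype is the difference between its mean registered
#' shapes at the two stages. The angle between two genotypes' change
#' vectors measures how similar their developmental transformations are:
#' 0 degrees means identical direction, 90 degrees independent change.
#'
#' @param g a `wing_gpa`, or an n x 2p shape matrix.
#' @param stage,genotype labels; default from `g$info`.
#' @param transitions list of length-2 character vectors
#'   (`c(from, to)`); default the three stage transitions.
#' @return data.frame of class `trajectory_angles` with columns
#'   `transition`, `genotype_1`, `genotype_2`, `angle_deg` (in
#'   \[0, 180\]).
#' @export
trajectory_angles <- function(g, stage = NULL, genotype = NULL,
                              transitions = list(c("larva", "pupa"),
                                                 c("pupa", "adult"),
                                                 c("larva", "adult"))) {
  Y <- if (inherits(g, "wing_gpa")) g$shapes else as.matrix(g)
  if (is.null(stage)) stage <- g$info$stage
  if (is.null(genotype)) genotype <- g$info$genotype
  genos <- union(intersect(GENOTYPES, unique(genotype)), unique(genotype))
  rows <- list()
  for (tr in transitions) {
    stopifnot(length(tr) == 2)
    vecs <- lapply(genos, function(gn) {
      i1 <- stage == tr[1] & genotype == gn
      i2 <- stage == tr[2] & genotype == gn
      if (!any(i1) || !any(i2))
        stop("genotype ", gn, " missing a stage for transition ",
             paste(tr, collapse = " to "))
      v <- colMeans(Y[i2, , drop = FALSE]) - colMeans(Y[i1, , drop = FALSE])
      nv <- sqrt(sum(v^2))
      if (nv == 0)
        stop("zero-length shape-change vector for genotype ", gn,
             " (", paste(tr, collapse = " to "), "): angle undefined")
      v / nv
    })
    names(vecs) <- genos
    for (a in seq_along(genos)) for (b in seq(a, length(genos))) {
      cosang <- min(1, max(-1, sum(vecs[[a]] * vecs[[b]])))
      rows[[length(rows) + 1L]] <- data.frame(
        transition = paste(tr, collapse = "_to_"),
        genotype_1 = genos[a], genotype_2 = genos[b],
        angle_deg = acos(cosang) * 180 / pi,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("trajectory_angles", class(out))
  out
}

#' Angle between two shape-change vectors
#'
#' @param v1,v2 numeric vectors of equal length.
#' @return angle in degrees, in \[0, 180\].
#' @export
vector_angle <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length vector: angle undefined")
  acos(min(1, max(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}
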