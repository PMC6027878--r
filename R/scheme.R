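#' Landmark scheme for the developing wing
#'
#' The measurement scheme places 8 fixed landmarks and 9 semilandmarks on
#' each wing. Landmarks 1, 3, 5 and 7 sit on the dorso-ventral
#' boundary/wing margin at its intersections with (pro)veins L1, L3, L4
#' and L5; landmarks 2, 4, 6 and 8 mark the proximal ends of those veins.
#' Semilandmarks 9-14 follow the margin between landmarks 1 and 3
#' (anterior), and 15-17 follow it between landmarks 5 and 7 (posterior).
#' Semilandmarks carry information only perpendicular to the margin, so
#' their tangential position is slid during superimposition.
#'
#' @return A list of class `wing_scheme` with elements
#'   `n_landmarks` (17), `n_fixed` (8), and `semi_groups`, a list of
#'   semilandmark groups, each holding `anchor_start`, `semis` (ordered
#'   indices) and `anchor_end`.
#' @export
#' @examples
#' s <- wing_scheme()
#' s$semi_groups$anterior$semis
wing_scheme <- function() {
  structure(list(
    n_landmarks = 17L,
    n_fixed = 8L,
    semi_groups = list(
      anterior  = list(anchor_start = 1L, semis = 9:14,  anchor_end = 3L),
      posterior = list(anchor_start = 5L, semis = 15:17, anchor_end = 7L)
    )
  ), class = "wing_scheme")
}

#' @export
print.wing_scheme <- function(x, ...) {
  cat("Wing landmark scheme:", x$n_landmarks, "points (",
      x$n_fixed, "fixed )\n")
  for (nm in names(x$semi_groups)) {
    g <- x$semi_groups[[nm]]
    cat(sprintf("  %s semilandmarks %s anchored by landmarks %d and %d\n",
                nm, paste(range(g$semis), collapse = "-"),
                g$anchor_start, g$anchor_end))
  }
  invisible(x)
}

# semilandmark indices, in scheme order
semi_indices <- function(scheme) {
  sort(unlist(lapply(scheme$semi_groups, `[[`, "semis"), use.names = FALSE))
}

STAGES <- c("larva", "pupa", "adult")
GENOTYPES <- c("yw", "ds", "shf2")

#' Bundle landmark configurations with specimen metadata
#'
#' The container used throughout the package: a p x 2 x n array of
#' landmark coordinates (mm) plus one metadata row per specimen.
#'
#' @param coords 17 x 2 x n numeric array (or a 17 x 2 matrix for n = 1).
#'   Row k is landmark k of the scheme.
#' @param info data.frame with columns `id`, `stage`, `genotype`, `sex`
#'   (one row per specimen). `id` must be unique. Extra columns are kept.
#' @param scheme a [wing_scheme()].
#' @return An object of class `wing_set`: list with `coords`, `info`,
#'   `scheme`.
#' @export
wing_set <- function(coords, info, scheme = wing_scheme()) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 2L, 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  if (dim(coords)[1] != scheme$n_landmarks)
    stop("expected ", scheme$n_landmarks, " landmarks per specimen, got ",
         dim(coords)[1])
  if (!all(is.finite(coords)))
    stop("non-finite landmark coordinates")
  info <- as.data.frame(info)
  req <- c("id", "stage", "genotype", "sex")
  miss <- setdiff(req, names(info))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(info) != dim(coords)[3])
    stop("metadata rows (", nrow(info), ") != specimens (", dim(coords)[3], ")")
  info$id <- as.character(info$id)
  if (anyDuplicated(info$id))
    stop("duplicate specimen id(s): ",
         paste(unique(info$id[duplicated(info$id)]), collapse = ", "))
  dimnames(coords) <- list(NULL, c("x", "y"), info$id)
  structure(list(coords = coords, info = info, scheme = scheme),
            class = "wing_set")
}

#' @export
print.wing_set <- function(x, ...) {
  cat("wing_set:", dim(x$coords)[3], "specimens,",
      dim(x$coords)[1], "landmarks\n")
  print(table(stage = x$info$stage, genotype = x$info$genotype))
  invisible(x)
}

#' Number of specimens in a wing_set
#' @param x a `wing_set`
#' @return integer count
#' @export
n_specimens <- function(x) dim(x$coords)[3]

#' Subset a wing_set by specimen
#' @param x a `wing_set`
#' @param i logical, integer or character (id) index
#' @return a `wing_set` with the selected specimens
#' @export
subset_wings <- function(x, i) {
  if (is.character(i)) i <- match(i, x$info$id)
  if (anyNA(i)) stop("unknown specimen id in subset")
  wing_set(x$coords[, , i, drop = FALSE], x$info[i, , drop = FALSE],
           x$scheme)
}

# flatten p x 2 x n -> n x 2p rows (x1,y1,x2,y2,...)
flatten_shapes <- function(coords) {
  p <- dim(coords)[1]; n <- dim(coords)[3]
  out <- matrix(NA_real_, n, 2L * p)
  for (j in seq_len(p)) {
    out[, 2L * j - 1L] <- coords[j, 1L, ]
    out[, 2L * j] <- coords[j, 2L, ]
  }
  colnames(out) <- paste0(rep(c("x", "y"), p), rep(seq_len(p), each = 2L))
  out
}

# inverse of flatten_shapes
unflatten_shapes <- function(mat) {
  p <- ncol(mat) / 2L
  n <- nrow(mat)
  arr <- array(NA_real_, c(p, 2L, n))
  for (j in seq_len(p)) {
    arr[j, 1L, ] <- mat[, 2L * j - 1L]
    arr[j, 2L, ] <- mat[, 2L * j]
  }
  dimnames(arr) <- list(NULL, c("x", "y"), rownames(mat))
  arr
}

# evaluate fn with a temporary RNG state seeded by `seed` (NULL = use
# current stream)
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}
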