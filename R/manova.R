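# ---- Type III Wilks machinery ----------------------------------------

# Build the fixed design for a full factorial of the supplied factors
# with sum-to-zero contrasts, plus the reduced design for each term
# (full design minus that term's columns). With contr.sum coding,
# comparing residual cross-products of full vs reduced design tests the
# marginal (each-effect-last, "Type III") hypothesis for the term.
design_precompute <- function(factors) {
  factors <- as.data.frame(factors)
  factors[] <- lapply(factors, factor)
  fml <- stats::as.formula(paste("~", paste(names(factors), collapse = "*")))
  X <- stats::model.matrix(fml, factors,
                           contrasts.arg = lapply(factors, function(.)
                             "contr.sum"))
  asgn <- attr(X, "assign")
  terms_lab <- attr(stats::terms(fml), "term.labels")
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design (aliased terms): ",
         paste(terms_lab, collapse = ", "))
  qr_full <- qr(X)
  qr_red <- lapply(seq_along(terms_lab), function(t) {
    qr(X[, asgn != t, drop = FALSE])
  })
  names(qr_red) <- terms_lab
  list(X = X, qr_full = qr_full, qr_red = qr_red, terms = terms_lab,
       asgn = asgn, n = nrow(X))
}

logdet <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  2 * sum(log(diag(ch)))
}

# Wilks' lambda for one term given a precomputed design
wilks_stat <- function(Y, pre, effect) {
  if (!effect %in% pre$terms)
    stop("unknown effect '", effect, "'; design terms are: ",
         paste(pre$terms, collapse = ", "))
  if (ncol(Y) > pre$n - pre$qr_full$rank)
    stop("singular error matrix: response dimension (", ncol(Y),
         ") exceeds error df (", pre$n - pre$qr_full$rank,
         "); use fewer PCs")
  E <- crossprod(qr.resid(pre$qr_full, Y))
  EH <- crossprod(qr.resid(pre$qr_red[[effect]], Y))
  ld_e <- logdet(E)
  if (is.na(ld_e))
    stop("singular error matrix: response dimension (", ncol(Y),
         ") too large for error df (", pre$n - pre$qr_full$rank,
         "); use fewer PCs")
  min(1, exp(ld_e - logdet(EH)))
}

#' MANOVA Wilks' lambda with Type III cross-products
#'
#' Computes Wilks' lambda = det(E) / det(E + H) for one effect of a fully
#' crossed factorial design, where E and H are the error and hypothesis
#' sums-of-squares-and-cross-products matrices under marginal
#' (each-effect-last, Type III) hypotheses with sum-to-zero contrasts. A
#' parametric p-value from Rao's F approximation is included; for
#' cross-stage wing comparisons prefer [randomized_manova()], since shape
#' variance differs strongly among stages.
#'
#' @param Y n x p response matrix (e.g. retained PC scores).
#' @param factors data.frame of factors (crossed design is built from all
#'   columns).
#' @param effect term label to test, e.g. `"genotype"` or
#'   `"stage:genotype"`.
#' @return list: `lambda`, `df_num`, `df_den` (Rao approximation),
#'   `F`, `p_value`, `effect`.
#' @export
manova_wilks <- function(Y, factors, effect) {
  Y <- as.matrix(Y)
  pre <- design_precompute(factors)
  lam <- wilks_stat(Y, pre, effect)
  p <- ncol(Y)
  q <- sum(pre$asgn == match(effect, pre$terms))
  v <- pre$n - pre$qr_full$rank
  if (p >= v + p) {} # unreachable; singularity handled in wilks_stat
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- v + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * tt - (p * q) / 2 + 1
  lam_t <- lam^(1 / tt)
  Fstat <- if (lam_t > 0) (1 - lam_t) / lam_t * df2 / df1 else Inf
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(lambda = lam, df_num = df1, df_den = df2, F = Fstat,
       p_value = pval, effect = effect)
}

# ---- mean-residual decomposition and randomization test ---------------

#' Decompose shapes into grand mean and factor residual means
#'
#' Writes every observation as grand mean + stage residual mean +
#' genotype residual mean + stage-by-genotype residual mean + individual
#' deviation. The reconstruction is exact by construction. With
#' `weighted = FALSE` (default, matching the Type III spirit used for
#' testing) marginal and grand means are unweighted means of cell means,
#' so each residual-mean set sums to zero over its index; with
#' `weighted = TRUE` they are observation-weighted.
#'
#' @param Y n x k shape (or score) matrix.
#' @param stage,genotype factor labels, length n. Every (stage, genotype)
#'   cell must be non-empty.
#' @param weighted use observation-weighted marginal means.
#' @return list of class `shape_decomposition`: `grand` (k-vector),
#'   `stage_res` / `genotype_res` / `cell_res` (residual-mean matrices,
#'   one row per level or cell), `eps` (n x k individual deviations),
#'   plus the label vectors and the cell key per observation.
#' @export
decompose_shapes <- function(Y, stage, genotype, weighted = FALSE) {
  Y <- as.matrix(Y)
  stage <- factor(stage); genotype <- factor(genotype)
  stopifnot(length(stage) == nrow(Y), length(genotype) == nrow(Y))
  tab <- table(stage, genotype)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(paste(rownames(tab)[empty[, 1]],
                     colnames(tab)[empty[, 2]], sep = "/"),
               collapse = ", "))
  }
  cell_key <- interaction(stage, genotype, sep = "/", drop = TRUE)
  cells <- levels(cell_key)
  cell_mean <- t(vapply(cells, function(cl)
    colMeans(Y[cell_key == cl, , drop = FALSE]), numeric(ncol(Y))))
  cell_stage <- factor(sub("/.*", "", cells), levels = levels(stage))
  cell_geno <- factor(sub(".*/", "", cells), levels = levels(genotype))
  if (weighted) {
    grand <- colMeans(Y)
    smean <- t(vapply(levels(stage), function(s)
      colMeans(Y[stage == s, , drop = FALSE]), numeric(ncol(Y))))
    gmean <- t(vapply(levels(genotype), function(g)
      colMeans(Y[genotype == g, , drop = FALSE]), numeric(ncol(Y))))
  } else {
    grand <- colMeans(cell_mean)
    smean <- t(vapply(levels(stage), function(s)
      colMeans(cell_mean[cell_stage == s, , drop = FALSE]),
      numeric(ncol(Y))))
    gmean <- t(vapply(levels(genotype), function(g)
      colMeans(cell_mean[cell_geno == g, , drop = FALSE]),
      numeric(ncol(Y))))
  }
  stage_res <- sweep(smean, 2, grand)
  genotype_res <- sweep(gmean, 2, grand)
  cell_res <- cell_mean -
    matrix(grand, nrow(cell_mean), ncol(Y), byrow = TRUE) -
    stage_res[as.integer(cell_stage), , drop = FALSE] -
    genotype_res[as.integer(cell_geno), , drop = FALSE]
  eps <- Y - cell_mean[as.integer(cell_key), , drop = FALSE]
  structure(list(grand = grand, stage_res = stage_res,
                 genotype_res = genotype_res, cell_res = cell_res,
                 eps = eps, stage = stage, genotype = genotype,
                 cell_key = cell_key),
            class = "shape_decomposition")
}

#' Reconstruct observations from a decomposition
#' @param dec a `shape_decomposition`.
#' @return n x k matrix equal (to machine precision) to the input of
#'   [decompose_shapes()].
#' @export
reconstruct_shapes <- function(dec) {
  n <- nrow(dec$eps); k <- length(dec$grand)
  matrix(dec$grand, n, k, byrow = TRUE) +
    dec$stage_res[as.integer(dec$stage), , drop = FALSE] +
    dec$genotype_res[as.integer(dec$genotype), , drop = FALSE] +
    dec$cell_res[as.integer(dec$cell_key), , drop = FALSE] +
    dec$eps
}

#' Randomization MANOVA on Wilks' lambda
#'
#' Tests a genotype main effect or a stage-by-genotype interaction while
#' respecting the strongly stage-dependent shape variance (which breaks
#' the homogeneity assumption of parametric MANOVA). Each observation is
#' decomposed via [decompose_shapes()]; randomized datasets are built by
#' permuting, among individuals, the residual-mean component under test
#' *together with the individual deviation* (genotype effect:
#' `R_g + eps`; interaction: `R_sg + eps`), holding all other components
#' fixed, and Wilks' lambda is recomputed for the same Type III effect.
#' Bundling the individual deviation makes the observed dataset a member
#' of the permutation family (the identity permutation), which is what
#' calibrates the test; permuting the residual-mean component alone
#' produces null sets with systematically diluted group-mean sampling
#' noise and a badly anti-conservative test. Permutations are within
#' stages by default, preserving the stage-specific variance; the
#' across-all-individuals variant is available for the genotype effect
#' but is mis-calibrated when stages differ in variance.
#'
#' @param Y n x p response matrix (retained PC scores by default
#'   upstream).
#' @param stage,genotype factor labels.
#' @param effect `"genotype"` or `"interaction"`.
#' @param n_rand number of randomized datasets (study convention: 1000).
#' @param seed RNG seed.
#' @param genotype_permutation for the genotype main effect:
#'   `"within_stage"` (default) or `"across_all"`.
#' @param weighted passed to [decompose_shapes()].
#' @return list of class `randomization_result`: `effect`,
#'   `observed_lambda`, `null_lambdas`, `p_value` (add-one estimator),
#'   `n_rand`, `seed`, `permutation`.
#' @export
randomized_manova <- function(Y, stage, genotype,
                              effect = c("genotype", "interaction"),
                              n_rand = 1000L, seed = NULL,
                              genotype_permutation = c("within_stage",
                                                       "across_all"),
                              weighted = FALSE) {
  effect <- match.arg(effect)
  genotype_permutation <- match.arg(genotype_permutation)
  stopifnot(n_rand >= 1)
  Y <- as.matrix(Y)
  dec <- decompose_shapes(Y, stage, genotype, weighted = weighted)
  pre <- design_precompute(data.frame(stage = dec$stage,
                                      genotype = dec$genotype))
  term <- if (effect == "genotype") "genotype" else "stage:genotype"
  observed <- wilks_stat(Y, pre, term)
  n <- nrow(Y)
  base <- matrix(dec$grand, n, ncol(Y), byrow = TRUE) +
    dec$stage_res[as.integer(dec$stage), , drop = FALSE]
  geno_part <- dec$genotype_res[as.integer(dec$genotype), , drop = FALSE]
  cell_part <- dec$cell_res[as.integer(dec$cell_key), , drop = FALSE]
  # the permuted block carries the tested component plus the individual
  # deviation; the complementary component stays attached to the design
  moved <- if (effect == "genotype") geno_part + dec$eps
  else cell_part + dec$eps
  held <- if (effect == "genotype") cell_part else geno_part
  within_stage <- effect == "interaction" ||
    genotype_permutation == "within_stage"
  stage_idx <- split(seq_len(n), dec$stage)
  null_lambdas <- with_seed(seed, function() {
    vapply(seq_len(n_rand), function(r) {
      if (within_stage) {
        perm <- seq_len(n)
        for (ix in stage_idx) perm[ix] <- ix[sample.int(length(ix))]
      } else {
        perm <- sample(n)
      }
      wilks_stat(base + held + moved[perm, , drop = FALSE], pre, term)
    }, 0)
  })
  p_value <- (1 + sum(null_lambdas <= observed)) / (n_rand + 1)
  structure(list(effect = effect, observed_lambda = observed,
                 null_lambdas = null_lambdas, p_value = p_value,
                 n_rand = n_rand, seed = seed,
                 permutation = if (effect == "genotype")
                   genotype_permutation else "within_stage"),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "randomization MANOVA (%s): observed Wilks' lambda = %.4g, min null = %.4g, p = %.4g (%d randomizations, %s permutation)\n",
    x$effect, x$observed_lambda, min(x$null_lambdas), x$p_value,
    x$n_rand, x$permutation))
  invisible(x)
}
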