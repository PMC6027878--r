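test_that("shape_pca: trace conservation, degenerate data, SVD oracle", {
  set.seed(8)
  Y <- matrix(rnorm(30 * 12), 30, 12)
  p <- shape_pca(Y, n_axes = 5)
  expect_equal(sum(p$eigenvalues), sum(diag(cov(Y))), tolerance = 1e-10)
  # scores match direct SVD up to sign
  Yc <- sweep(Y, 2, colMeans(Y))
  sv <- svd(Yc)
  for (j in 1:5) {
    ref <- Yc %*% sv$v[, j]
    expect_equal(as.numeric(abs(cor(p$scores[, j], ref))), 1,
                 tolerance = 1e-10)
  }
  # projection back reproduces the centered data within retained subspace
  p_all <- shape_pca(Y, n_axes = 12)
  expect_lt(max(abs(p_all$scores %*% t(p_all$loadings) - Yc)), 1e-10)
  # variation confined to one coordinate pair
  Z <- matrix(0, 20, 6)
  Z[, 1] <- rnorm(20); Z[, 2] <- 2 * Z[, 1]   # rank-1 variation
  pz <- suppressWarnings(shape_pca(Z, n_axes = 2))
  expect_lt(pz$eigenvalues[2] / pz$eigenvalues[1], 1e-12)
  expect_warning(shape_pca(Z, n_axes = 5), "rank")
})

test_that("cva separates separated classes and spheres within-class
           scatter", {
  set.seed(9)
  X <- rbind(cbind(rnorm(20, 0, 0.01), rnorm(20, 0, 0.01)),
             cbind(rnorm(20, 10, 0.01), rnorm(20, 0, 0.01)))
  lab <- rep(c("a", "b"), each = 20)
  cv <- cva(X, lab)
  expect_equal(ncol(cv$scores), 1)
  gap <- abs(mean(cv$scores[lab == "a", 1]) - mean(cv$scores[lab == "b", 1]))
  wsd <- sd(c(cv$scores[lab == "a", 1] - mean(cv$scores[lab == "a", 1]),
              cv$scores[lab == "b", 1] - mean(cv$scores[lab == "b", 1])))
  expect_gt(gap / wsd, 100)

  # permuted labels: no separation
  Xn <- matrix(rnorm(200 * 4), 200, 4)
  labs <- sample(rep(c("a", "b", "c"), length.out = 200))
  cvn <- cva(Xn, labs)
  expect_lt(max(cvn$eigenvalues), 0.2)

  # three synthetic stages are disjoint on the canonical plane
  d <- generate_dataset(small_config(n = 8, seed = 23))
  s <- slide_semilandmarks(gpa(d))
  sc <- shape_pca(s, 18)$scores
  cv3 <- cva(sc, s$info$stage)
  expect_equal(ncol(cv3$scores), 2)
  cent <- vapply(unique(s$info$stage), function(st)
    colMeans(cv3$scores[s$info$stage == st, , drop = FALSE]), numeric(2))
  assign_to <- apply(cv3$scores, 1, function(r)
    colnames(cent)[which.min(colSums((cent - r)^2))])
  expect_equal(unname(assign_to), s$info$stage)

  expect_error(cva(X, rep("a", 40)), "2 classes")
  expect_error(cva(cbind(X, X), lab), "singular")
})

test_that("manova_wilks: hand-computed and reference oracles", {
  # univariate two-group: E = 1, H = 4, lambda = 0.2
  y <- matrix(c(0, 1, 2, 3), 4, 1)
  f <- data.frame(g = c("a", "a", "b", "b"))
  expect_equal(manova_wilks(y, f, "g")$lambda, 0.2, tolerance = 1e-12)

  # balanced random 4-variable 2-factor dataset vs stats::manova
  set.seed(10)
  fac <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                     rep = 1:5)[, 1:2]
  Y <- matrix(rnorm(nrow(fac) * 4), ncol = 4) +
    model.matrix(~ A + B, fac)[, -1] %*% matrix(runif(12), 3, 4)
  ref <- summary(manova(Y ~ A * B, data = fac), test = "Wilks")$stats
  for (eff in c("A", "B", "A:B"))
    expect_equal(manova_wilks(Y, fac, eff)$lambda,
                 ref[eff, "Wilks"], tolerance = 1e-8)

  # lambda bounded in (0, 1] under the null
  Y0 <- matrix(rnorm(60 * 3), 60, 3)
  lam <- manova_wilks(Y0, data.frame(g = rep(letters[1:3], 20)), "g")$lambda
  expect_gt(lam, 0); expect_lte(lam, 1)

  # too many responses for the error df
  expect_error(manova_wilks(matrix(rnorm(6 * 5), 6, 5),
                            data.frame(g = rep(c("a", "b"), 3)), "g"),
               "fewer PCs")
})

test_that("decompose_shapes reconstructs exactly and zeroes out
           degenerate structure", {
  set.seed(11)
  n <- 40
  stage <- sample(c("larva", "pupa", "adult"), n, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  geno <- sample(c("yw", "ds"), n, replace = TRUE)
  # ensure all cells non-empty
  stage[1:6] <- rep(c("larva", "pupa", "adult"), 2)
  geno[1:6] <- rep(c("yw", "ds"), each = 3)
  Y <- matrix(rnorm(n * 7), n, 7)
  for (w in c(FALSE, TRUE)) {
    dec <- decompose_shapes(Y, stage, geno, weighted = w)
    expect_lt(max(abs(reconstruct_shapes(dec) - Y)), 1e-12)
    # residual means sum to zero under the chosen weighting
    ws <- if (w) as.vector(table(factor(stage))[rownames(dec$stage_res)])
    else rep(1, nrow(dec$stage_res))
    wg <- if (w) as.vector(table(factor(geno))[rownames(dec$genotype_res)])
    else rep(1, nrow(dec$genotype_res))
    expect_lt(max(abs(colSums(dec$stage_res * ws))), 1e-10)
    expect_lt(max(abs(colSums(dec$genotype_res * wg))), 1e-10)
  }
  # one observation per cell: eps = 0
  f <- expand.grid(stage = c("larva", "pupa"), geno = c("yw", "ds"))
  Y1 <- matrix(rnorm(4 * 3), 4, 3)
  dec1 <- decompose_shapes(Y1, f$stage, f$geno)
  expect_lt(max(abs(dec1$eps)), 1e-12)
  # identical observations: all residual terms 0
  Yc <- matrix(1, 8, 2)
  dec2 <- decompose_shapes(Yc, rep(c("larva", "pupa"), 4),
                           rep(c("yw", "ds"), each = 4))
  expect_lt(max(abs(dec2$stage_res)), 1e-12)
  expect_lt(max(abs(dec2$cell_res)), 1e-12)
  expect_lt(max(abs(dec2$eps)), 1e-12)
  # empty cell
  expect_error(decompose_shapes(Y1[1:3, ], f$stage[1:3], f$geno[1:3]),
               "empty design cell")
})

test_that("randomized_manova: determinism, p-value bounds, strong-effect
           detection", {
  set.seed(12)
  n_per <- 6
  fac <- expand.grid(rep = 1:n_per, stage = c("larva", "pupa", "adult"),
                     geno = c("yw", "ds", "shf2"))
  Y <- matrix(rnorm(nrow(fac) * 8), ncol = 8)
  r1 <- randomized_manova(Y, fac$stage, fac$geno, "genotype",
                          n_rand = 99, seed = 4)
  r2 <- randomized_manova(Y, fac$stage, fac$geno, "genotype",
                          n_rand = 99, seed = 4)
  expect_identical(r1$null_lambdas, r2$null_lambdas)
  expect_gte(r1$p_value, 1 / 100)
  expect_lte(r1$p_value, 1)
  expect_true(all(r1$null_lambdas > 0 & r1$null_lambdas <= 1))

  # strong genotype effect: observed lambda below all randomized values
  eff <- matrix(0, nrow(fac), 8)
  eff[fac$geno == "ds", 1] <- 5
  eff[fac$geno == "shf2", 2] <- -5
  rs <- randomized_manova(Y + eff, fac$stage, fac$geno, "genotype",
                          n_rand = 200, seed = 5)
  expect_lt(rs$observed_lambda, min(rs$null_lambdas))
  expect_equal(rs$p_value, 1 / 201)

  # interaction randomization stays within stages and detects interaction
  eff_i <- matrix(0, nrow(fac), 8)
  eff_i[fac$geno == "ds" & fac$stage == "pupa", 3] <- 6
  eff_i[fac$geno == "ds" & fac$stage != "pupa", 3] <- -3
  ri <- randomized_manova(Y + eff_i, fac$stage, fac$geno, "interaction",
                          n_rand = 200, seed = 6)
  expect_lt(ri$p_value, 0.05)
})

test_that("mean shape distance matrix matches a brute-force double loop", {
  set.seed(13)
  Y <- matrix(rnorm(10 * 4), 10, 4)
  stage <- rep(c("larva", "pupa"), each = 5)
  geno <- rep(c("yw", "ds"), 5)
  M <- mean_shape_distance_matrix(Y, stage, geno)
  expect_true(isSymmetric(M))
  key <- paste(stage, geno, sep = "/")
  for (a in rownames(M)) for (b in colnames(M)) {
    ia <- which(key == a); ib <- which(key == b)
    acc <- c()
    for (i in ia) for (j in ib)
      if (i != j) acc <- c(acc, sqrt(sum((Y[i, ] - Y[j, ])^2)))
    expect_equal(M[a, b], mean(acc), tolerance = 1e-12)
  }
  # identical specimens -> zeros; singleton diagonal -> NA
  Y2 <- matrix(1, 4, 3)
  M2 <- mean_shape_distance_matrix(Y2, rep("larva", 4),
                                   c("yw", "yw", "yw", "ds"))
  expect_equal(M2["larva/yw", "larva/yw"], 0)
  expect_true(is.na(M2["larva/ds", "larva/ds"]))
  # two singletons differing by delta in one coordinate
  Y3 <- rbind(c(0, 0), c(0.3, 0))
  M3 <- mean_shape_distance_matrix(Y3, c("larva", "larva"), c("yw", "ds"))
  expect_equal(M3["larva/yw", "larva/ds"], 0.3)
})

test_that("trajectory angles: closed forms and invariances", {
  expect_equal(vector_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vector_angle(c(1, 2, 3), c(2, 4, 6)), 0)
  set.seed(14)
  v1 <- rnorm(6); v2 <- rnorm(6)
  expect_equal(vector_angle(v1, v2), vector_angle(v2, v1))
  expect_equal(vector_angle(v1, v2), vector_angle(3.7 * v1, 0.2 * v2),
               tolerance = 1e-10)
  expect_error(vector_angle(v1, rep(0, 6)), "zero-length")

  # identical transformations in two genotypes -> 0 degrees
  base <- matrix(rnorm(8), 4, 2)
  shiftv <- matrix(rnorm(8), 4, 2)
  Y <- rbind(c(t(base)), c(t(base + 0.1)),       # yw larva, ds larva
             c(t(base + shiftv)), c(t(base + 0.1 + shiftv)))
  ta <- trajectory_angles(Y, stage = c("larva", "larva", "pupa", "pupa"),
                          genotype = c("yw", "ds", "yw", "ds"),
                          transitions = list(c("larva", "pupa")))
  expect_equal(ta$angle_deg[ta$genotype_1 == "yw" & ta$genotype_2 == "ds"],
               0, tolerance = 1e-4)
  expect_true(all(ta$angle_deg >= 0 & ta$angle_deg <= 180))
})
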