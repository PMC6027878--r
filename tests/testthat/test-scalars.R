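test_that("standardize_config: closed form, idempotence, scale
           invariance", {
  sq17 <- matrix(0, 17, 2)
  sq17[1:4, ] <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  sq4 <- sq17[1:4, ]
  expect_equal(standardize_config(sq4), sq4 / sqrt(2))
  set.seed(19)
  m <- random_config()
  s <- standardize_config(m)
  expect_equal(centroid_size(s), 1, tolerance = 1e-12)
  expect_equal(standardize_config(s), s, tolerance = 1e-12)
  expect_equal(standardize_config(3 * m), s, tolerance = 1e-12)
})

test_that("pairwise_distances: 28 named values matching a double loop", {
  set.seed(20)
  m <- standardize_config(random_config())
  d <- pairwise_distances(m)
  expect_length(d, 28)
  expect_equal(names(d)[1], "stlen12")
  expect_equal(names(d)[28], "stlen78")
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(d[[paste0("stlen", i, j)]],
                 sqrt(sum((m[i, ] - m[j, ])^2)), tolerance = 1e-12)
  # collinear equally spaced landmarks
  lin <- cbind(seq(0, 1.6, by = 0.1), 0)
  dl <- pairwise_distances(lin)
  expect_equal(dl[["stlen13"]], 2 * dl[["stlen12"]], tolerance = 1e-12)
})

test_that("margin_length: straight segments, triangle inequality,
           arc quadrature", {
  m <- matrix(0, 17, 2)
  # anterior path 1,9..14,3 equally spaced on a straight segment length 2
  m[c(1, 9:14, 3), ] <- cbind(seq(0, 2, length.out = 8), 1)
  # posterior path 5,15:17,7 on a semicircle of radius 1
  th <- seq(pi, 0, length.out = 5)
  m[c(5, 15:17, 7), ] <- cbind(cos(th), sin(th))
  expect_equal(margin_length(m, "anterior"), 2, tolerance = 1e-12)
  arc <- margin_length(m, "posterior")
  expect_gte(arc, sqrt(sum((m[5, ] - m[7, ])^2)))  # >= anchor chord
  # chord approximation bound: deficit per chord ~ arc * h^2 / 24
  h <- pi / 4
  expect_lt(pi - arc, pi * h^2 / 20)
  expect_gt(pi - arc, 0)
})

test_that("polygon_area: unit square, triangle, fan-triangulation
           oracle, self-intersection warning", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq, vertices = 1:4), 1)
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(polygon_area(tri, vertices = 1:3), 0.5)
  expect_equal(polygon_area(tri[3:1, ], vertices = 1:3), 0.5) # orientation
  set.seed(21)
  for (r in 1:25) {
    v <- random_simple_polygon(sample(5:17, 1))
    expect_equal(polygon_area(v, vertices = seq_len(nrow(v))),
                 fan_area(v), tolerance = 1e-12)
  }
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_warning(polygon_area(bow, vertices = 1:4), "self-intersecting")
})

test_that("region polygons use the documented vertex paths", {
  tmpl <- wing_templates()$adult
  for (w in c("anterior", "middle", "posterior", "total")) {
    a <- polygon_area(tmpl, w)
    expect_gt(a, 0)
  }
  # middle region is the landmark 4,3,5,6 quadrilateral
  expect_equal(polygon_area(tmpl, "middle"),
               fan_area(tmpl[c(4, 3, 5, 6), ]), tolerance = 1e-12)
})

test_that("scalar_table emits the full schema with invariant
           standardized columns", {
  d <- generate_dataset(small_config(n = 3, seed = 25))
  tab <- suppressWarnings(scalar_table(d))
  expect_equal(sum(grepl("^stlen", names(tab))), 28)
  expect_true(all(c("anterior_margin_len", "posterior_margin_len",
                    "area_anterior", "area_middle", "area_posterior",
                    "area_total", "std_area_total", "centroid_size") %in%
                    names(tab)))
  # standardized scalars invariant under similarity transform of inputs
  d2 <- d
  for (i in seq_len(n_specimens(d)))
    d2$coords[, , i] <- similarity_transform(d2$coords[, , i], 1.1, 4.2,
                                             c(7, -3))
  tab2 <- suppressWarnings(scalar_table(d2))
  stdcols <- c(grep("^stlen", names(tab), value = TRUE),
               "anterior_margin_len", "posterior_margin_len",
               grep("^std_area", names(tab), value = TRUE))
  for (cl in stdcols)
    expect_equal(tab2[[cl]], tab[[cl]], tolerance = 1e-10)
  expect_equal(tab2$area_total, 4.2^2 * tab$area_total, tolerance = 1e-9)
})

test_that("bootstrap_ratio: degenerate groups, determinism, point
           estimate", {
  r <- bootstrap_ratio(rep(2, 5), rep(2, 7), n_boot = 50, seed = 1)
  expect_equal(r$point_ratio, 1)
  expect_true(all(r$boot == 1))
  expect_equal(r$ci, c(1, 1))

  set.seed(22)
  a <- rlnorm(15, 0, 0.2); b <- rlnorm(12, 0.5, 0.2)
  r1 <- bootstrap_ratio(a, b, n_boot = 200, seed = 9)
  r2 <- bootstrap_ratio(a, b, n_boot = 200, seed = 9)
  expect_identical(r1$boot, r2$boot)
  expect_equal(r1$point_ratio, mean(a) / mean(b))
  expect_true(r1$ci[1] <= r1$point_ratio && r1$point_ratio <= r1$ci[2])
  expect_error(bootstrap_ratio(a, numeric(0)), "length")
})

test_that("delta-method ratio SE matches closed form and Monte Carlo", {
  expect_equal(ratio_se_delta(2, 0, 1, 0), 0)
  expect_equal(ratio_se_delta(2, 0.2, 1, 0.1), 2 * sqrt(0.02),
               tolerance = 1e-12)
  # Monte Carlo oracle
  set.seed(23)
  aa <- rnorm(2e5, 2, 0.2); bb <- rnorm(2e5, 1, 0.1)
  # first-order delta method: agreement within a few percent
  expect_equal(ratio_se_delta(2, 0.2, 1, 0.1), sd(aa / bb),
               tolerance = 0.04)
  # symmetric in relative errors
  expect_equal(ratio_se_delta(2, 0.2, 1, 0.05),
               ratio_se_delta(2, 0.1, 1, 0.1), tolerance = 1e-12)
  expect_error(ratio_se_delta(2, 0.2, 0, 0.1), "zero")

  t0 <- ratio_diff_test(2.4, 0.1, 2.4, 0.2)
  expect_equal(t0$p_value, 1)
  expect_lt(ratio_diff_test(54, 4, 35, 2)$p_value, 0.001)
})

test_that("fit_factorial: one-way oracle, interaction dropping, rank
           errors", {
  set.seed(24)
  y <- rnorm(20) + rep(c(0, 1.5), each = 10)
  f <- data.frame(genotype = rep(c("yw", "ds"), each = 10))
  fit <- fit_factorial(y, f)
  ref <- anova(lm(y ~ f$genotype))
  expect_equal(fit$anova$F[1], ref$`F value`[1], tolerance = 1e-10)
  expect_equal(fit$anova$p_value[1], ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(nrow(fit$tukey), 1)

  # pure main effects: the noise-free interaction is dropped
  g <- expand.grid(genotype = c("yw", "ds", "shf2"),
                   stage = c("larva", "pupa"), rep = 1:4)[, 1:2]
  y2 <- as.numeric(g$genotype) + 2 * as.numeric(g$stage) +
    rnorm(nrow(g), 0, 0.5)
  fit2 <- fit_factorial(y2, g)
  expect_true("genotype:stage" %in% fit2$dropped ||
                "stage:genotype" %in% fit2$dropped)
  expect_equal(nrow(fit2$tukey), 3)
  expect_true(all(fit2$tukey$p_adj >= 0 & fit2$tukey$p_adj <= 1))

  g$dup <- g$genotype
  expect_error(fit_factorial(y2, g), "rank-deficient")

  # log10 transform demands positive traits
  expect_error(fit_factorial(c(-1, y2[-1]), g[, 1:2],
                             log10_transform = TRUE))
})

test_that("null calibration: factorial F-test p-values are uniform
           enough", {
  set.seed(25)
  rej <- 0
  for (r in 1:200) {
    y <- rnorm(24)
    f <- data.frame(genotype = rep(c("yw", "ds", "shf2"), 8))
    p <- fit_factorial(y, f)$anova$p_value[1]
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / 200, 0.01)
  expect_lte(rej / 200, 0.10)
})
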