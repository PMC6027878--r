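#' Reference sample sizes and wing areas by stage and genotype
#'
#' Published group summaries for the three genotypes (yw wild-type,
#' ds = ds1/ds05142 trans-heterozygote, shf2) at the three developmental
#' stages: sample size (with sex counts) and the mean (SD) of the
#' anterior, middle, posterior and total polygon areas in mm^2. These are
#' the defaults that parameterize the synthetic-data generator (lognormal
#' size law) and the inputs to the ratio-of-means growth-factor
#' calculations.
#'
#' @return data.frame with columns `stage`, `genotype`, `n`, `n_female`,
#'   `n_male`, and `<region>_mean` / `<region>_sd` for the four regions.
#' @export
area_reference <- function() {
  df <- read.csv(text = "
stage,genotype,n,n_female,n_male,anterior_mean,anterior_sd,middle_mean,middle_sd,posterior_mean,posterior_sd,total_mean,total_sd
larva,yw,16,10,6,0.0053,0.0008,0.0016,0.0003,0.0029,0.0005,0.0100,0.0014
larva,shf2,8,5,3,0.0041,0.0003,0.0009,0.0001,0.0025,0.0004,0.0075,0.0008
larva,ds,8,1,7,0.0056,0.0016,0.0014,0.0004,0.0031,0.0008,0.0101,0.0027
pupa,yw,15,6,9,0.0125,0.0023,0.0034,0.0007,0.0079,0.0016,0.0240,0.0039
pupa,shf2,15,6,9,0.0107,0.0030,0.0014,0.0004,0.0055,0.0015,0.0177,0.0047
pupa,ds,12,4,8,0.0108,0.0024,0.0032,0.0005,0.0064,0.0014,0.0205,0.0041
adult,yw,6,2,4,0.375,0.040,0.142,0.017,0.326,0.036,0.843,0.085
adult,shf2,16,8,8,0.383,0.040,0.092,0.011,0.309,0.036,0.784,0.083
adult,ds,12,9,3,0.486,0.051,0.199,0.019,0.427,0.050,1.112,0.119
", stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

# Build a wing-like 17-point template. The margin (dorso-ventral
# boundary) is the upper arc of an ellipse with semi-axes a (proximo-
# distal, x) and b (antero-posterior, y); the proximal landmarks 2,4,6,8
# sit on a shallower lower arc (depth fraction cc) whose x extent is
# contracted by bx (hinge contraction of the later stages). Angles in
# degrees from +x, decreasing along the margin from landmark 1 to 7.
make_template <- function(a, b, cc, bx = 1) {
  margin_deg <- c(170, 159.3, 148.6, 137.9, 127.1, 116.4, 105.7, 95,
                  78, 61.5, 45, 28.5, 12)
  # margin order: 1, 9-14, 3, 5, 15-17, 7
  idx <- c(1L, 9:14, 3L, 5L, 15:17, 7L)
  m <- matrix(NA_real_, 17, 2)
  t <- margin_deg * pi / 180
  m[idx, 1] <- a * cos(t)
  m[idx, 2] <- b * sin(t)
  base_deg <- c(170, 95, 78, 12) * pi / 180   # under landmarks 1,3,5,7
  bidx <- c(2L, 4L, 6L, 8L)
  m[bidx, 1] <- bx * a * cos(base_deg)
  m[bidx, 2] <- -cc * b * sin(base_deg)
  m <- sweep(m, 2, colMeans(m))
  m / centroid_size(m)
}

#' Stage template shapes
#'
#' Hard-coded 17-point mean configurations for the three stages, at unit
#' centroid size: a near-circular larval wing pouch, a paddle-shaped 5 h
#' pupal wing, and an elongated adult blade. They are package fixtures
#' qualitatively matching the measured outlines, not estimates of the
#' real mean shapes.
#'
#' @return named list of 17 x 2 matrices (`larva`, `pupa`, `adult`).
#' @export
wing_templates <- function() {
  list(
    larva = make_template(0.95, 1.15, 0.95, 1.00),
    pupa  = make_template(1.70, 0.85, 0.38, 1.00),
    adult = make_template(3.20, 0.50, 0.18, 0.60)
  )
}

# center columns and scale to unit Frobenius norm
unit_effect <- function(d) {
  d <- sweep(d, 2, colMeans(d))
  n <- sqrt(sum(d^2))
  if (n == 0) stop("zero effect direction")
  d / n
}

#' Default genotype shape effects
#'
#' Mean shape displacements (17 x 2, shape units, column-centered) added
#' to the stage template for each genotype. yw is the reference (zero
#' effect). The ds pattern contracts the distal wing along the
#' proximo-distal axis at the larval stage and broadens the wing along
#' the antero-posterior axis from the pupal stage on. The shf2 pattern
#' pulls landmarks 3,4 (vein L3) and 5,6 (vein L4) together at every
#' stage, emulating the reduced L3-L4 spacing. Effect magnitudes
#' (Procrustes norm of the displacement) are derived from the reported
#' within- vs between-genotype mean shape distances at each stage.
#'
#' @param templates stage templates, see [wing_templates()].
#' @return nested list: `effects[[genotype]][[stage]]` -> 17 x 2 matrix.
#' @export
genotype_shape_effects <- function(templates = wing_templates()) {
  zero <- matrix(0, 17, 2)
  norms <- list(
    ds   = c(larva = 0.086, pupa = 0.136, adult = 0.105),
    shf2 = c(larva = 0.116, pupa = 0.129, adult = 0.067)
  )
  ds_dir <- function(tmpl, stage) {
    d <- matrix(0, 17, 2)
    if (stage == "larva") {
      # distal proximo-distal contraction: pull distal-half points inward
      d[, 1] <- -pmax(0, tmpl[, 1])
    } else {
      # antero-posterior broadening
      d[, 2] <- tmpl[, 2]
      if (stage == "adult") {
        # landmarks 4 and 6 shifted distally
        d[c(4, 6), 1] <- 0.5 * max(tmpl[, 1])
      }
    }
    unit_effect(d)
  }
  shf_dir <- function(tmpl) {
    d <- matrix(0, 17, 2)
    d[3, ] <- (tmpl[5, ] - tmpl[3, ]) / 2
    d[5, ] <- (tmpl[3, ] - tmpl[5, ]) / 2
    d[4, ] <- (tmpl[6, ] - tmpl[4, ]) / 2
    d[6, ] <- (tmpl[4, ] - tmpl[6, ]) / 2
    unit_effect(d)
  }
  out <- list(yw = list(larva = zero, pupa = zero, adult = zero))
  out$ds <- lapply(stats::setNames(STAGES, STAGES), function(s)
    norms$ds[[s]] * ds_dir(templates[[s]], s))
  out$shf2 <- lapply(stats::setNames(STAGES, STAGES), function(s)
    norms$shf2[[s]] * shf_dir(templates[[s]]))
  out
}

#' Simulation configuration
#'
#' Bundles everything [generate_dataset()] needs. Defaults state the
#' study's sampling design: group sizes and lognormal total-area law from
#' [area_reference()], stage templates from [wing_templates()], genotype
#' effects from [genotype_shape_effects()], and stage-specific isotropic
#' per-coordinate shape noise calibrated to the reported within-genotype
#' mean shape distances (see `noise_sd`).
#'
#' @param groups data.frame with columns `stage`, `genotype`, `n`,
#'   `area_mean`, `area_cv` (lognormal total-area mean, mm^2, and
#'   coefficient of variation).
#' @param templates,effects see [wing_templates()],
#'   [genotype_shape_effects()].
#' @param noise_sd named numeric, per-stage isotropic per-coordinate
#'   shape noise SD (shape units), calibrated so that mean pairwise
#'   shape distances between aligned specimens of the same genotype and
#'   stage are about 0.11 (larva), 0.17 (pupa) and 0.03 (adult)
#'   centroid-size units, preserving the reported ordering
#'   pupa > larva > adult.
#' @param sex_ratio probability a specimen is female.
#' @param seed integer RNG seed used by [generate_dataset()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(groups = NULL,
                       templates = wing_templates(),
                       effects = genotype_shape_effects(templates),
                       noise_sd = c(larva = 0.012, pupa = 0.029,
                                    adult = 0.0035),
                       sex_ratio = 0.5,
                       seed = 1L) {
  if (is.null(groups)) {
    ref <- area_reference()
    groups <- data.frame(stage = ref$stage, genotype = ref$genotype,
                         n = ref$n, area_mean = ref$total_mean,
                         area_cv = ref$total_sd / ref$total_mean)
  }
  stopifnot(all(c("stage", "genotype", "n", "area_mean", "area_cv") %in%
                  names(groups)),
            all(groups$n >= 0), all(noise_sd >= 0),
            sex_ratio >= 0, sex_ratio <= 1)
  for (s in unique(groups$stage)) {
    if (is.null(templates[[s]]))
      stop("no template for stage '", s, "'")
    if (centroid_size(templates[[s]]) <= 0)
      stop("degenerate template for stage '", s, "'")
    if (is.na(noise_sd[s]))
      stop("no noise SD for stage '", s, "'")
  }
  structure(list(groups = groups, templates = templates, effects = effects,
                 noise_sd = noise_sd, sex_ratio = sex_ratio,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# lognormal parameterized by mean and cv
rlnorm_meancv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Generate a synthetic landmark dataset
#'
#' For each (stage, genotype) group, draws `n` specimens as
#' template + genotype effect + i.i.d. Gaussian coordinate noise, then
#' rescales each configuration uniformly so its total polygon area
#' follows the group's lognormal size law. A pure function of the seed:
#' the same `config` always yields a bit-identical dataset. Groups are
#' generated in the fixed row order of `config$groups`, so the single
#' RNG stream assigns each group a deterministic sub-stream.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return a [wing_set()] with attribute `truth`: list with the
#'   noiseless group mean shapes (`group_means`, unit scale), the effect
#'   matrices and the noise SDs.
#' @export
generate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, function() {
    coords <- list(); info <- list(); means <- list()
    for (r in seq_len(nrow(config$groups))) {
      g <- config$groups[r, ]
      if (g$n == 0) next
      tmpl <- config$templates[[g$stage]]
      eff <- config$effects[[g$genotype]][[g$stage]]
      if (is.null(eff)) eff <- matrix(0, nrow(tmpl), 2)
      mean_shape <- tmpl + eff
      means[[paste(g$stage, g$genotype, sep = ".")]] <- mean_shape
      sd <- config$noise_sd[[g$stage]]
      areas <- rlnorm_meancv(g$n, g$area_mean, g$area_cv)
      sexes <- ifelse(stats::runif(g$n) < config$sex_ratio, "F", "M")
      for (i in seq_len(g$n)) {
        m <- mean_shape + matrix(stats::rnorm(34, 0, sd), 17, 2)
        a0 <- polygon_area(m, "total", check = FALSE)
        m <- m * sqrt(areas[i] / a0)
        coords[[length(coords) + 1L]] <- m
        info[[length(info) + 1L]] <- data.frame(
          id = sprintf("%s_%s_%02d", g$stage, g$genotype, i),
          stage = g$stage, genotype = g$genotype, sex = sexes[i],
          stringsAsFactors = FALSE)
      }
    }
    if (!length(coords)) stop("config requests zero specimens")
    arr <- array(unlist(coords), c(17L, 2L, length(coords)))
    out <- wing_set(arr, do.call(rbind, info))
    attr(out, "truth") <- list(group_means = means,
                               effects = config$effects,
                               noise_sd = config$noise_sd)
    out
  })
}

#' Inject multivariate shape outliers into a group
#'
#' Displaces `count` randomly chosen specimens of one (stage, genotype)
#' group in a uniformly random direction of the 34-dimensional shape
#' space. `displacement_sd` is measured in per-coordinate units of the
#' group's shape noise SD: the displacement vector has Procrustes norm
#' `displacement_sd * noise_sd * sqrt(34)`, applied on each specimen's
#' own scale (multiplied by its centroid size).
#'
#' @param x a [wing_set()] from [generate_dataset()].
#' @param stage,genotype group to contaminate.
#' @param count number of specimens to displace.
#' @param displacement_sd displacement magnitude, in group noise SDs per
#'   coordinate. 0 leaves the data unchanged.
#' @param noise_sd the group's noise SD; taken from the `truth` attribute
#'   when present.
#' @param seed RNG seed.
#' @return list with `data` (modified `wing_set`) and `outlier_ids`
#'   (character, ground truth).
#' @export
inject_outliers <- function(x, stage, genotype, count, displacement_sd,
                            noise_sd = NULL, seed = NULL) {
  stopifnot(displacement_sd >= 0, count >= 0)
  in_group <- which(x$info$stage == stage & x$info$genotype == genotype)
  if (!length(in_group)) stop("no specimens in group ", stage, "/", genotype)
  if (count > length(in_group))
    stop("count (", count, ") exceeds group size (", length(in_group), ")")
  if (is.null(noise_sd)) {
    tr <- attr(x, "truth")
    if (is.null(tr)) stop("noise_sd not given and no truth attribute")
    noise_sd <- tr$noise_sd[[stage]]
  }
  if (count == 0 || displacement_sd == 0)
    return(list(data = x, outlier_ids = character()))
  with_seed(seed, function() {
    picked <- sample(in_group, count)
    for (i in picked) {
      u <- stats::rnorm(34)
      u <- u / sqrt(sum(u^2))
      delta <- matrix(u, 17, 2) * displacement_sd * noise_sd * sqrt(34)
      cs <- centroid_size(x$coords[, , i])
      x$coords[, , i] <- x$coords[, , i] + delta * cs
    }
    list(data = x, outlier_ids = x$info$id[picked])
  })
}
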