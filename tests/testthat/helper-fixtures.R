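# Small in-code fixtures shared across test files.

# a compact simulation config: n per group for the requested stages /
# genotypes, reference-like areas, default noise
small_config <- function(n = 6, stages = c("larva", "pupa", "adult"),
                         genotypes = c("yw", "ds", "shf2"), seed = 1L,
                         noise_sd = NULL) {
  ref <- area_reference()
  grid <- expand.grid(stage = stages, genotype = genotypes,
                      stringsAsFactors = FALSE)
  grid$n <- n
  m <- match(paste(grid$stage, grid$genotype),
             paste(ref$stage, ref$genotype))
  grid$area_mean <- ref$total_mean[m]
  grid$area_cv <- (ref$total_sd / ref$total_mean)[m]
  args <- list(groups = grid, seed = seed)
  if (!is.null(noise_sd)) args$noise_sd <- noise_sd
  do.call(sim_config, args)
}

# random valid 17-landmark configuration (non-degenerate almost surely)
random_config <- function() matrix(rnorm(34), 17, 2)

# rigid-motion + scale transform of a configuration
similarity_transform <- function(m, angle, scale, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * m %*% t(R), 2, -shift)
}

# star-shaped (hence simple) random polygon with k vertices
random_simple_polygon <- function(k) {
  ang <- sort(runif(k, 0, 2 * pi))
  r <- runif(k, 0.2, 1)
  cbind(r * cos(ang), r * sin(ang))
}

# fan-triangulation area oracle for a simple polygon
fan_area <- function(v) {
  a <- 0
  for (i in 2:(nrow(v) - 1)) {
    u <- v[i, ] - v[1, ]; w <- v[i + 1, ] - v[1, ]
    a <- a + (u[1] * w[2] - u[2] * w[1]) / 2
  }
  abs(a)
}

# brute-force rotation-grid Procrustes distance oracle
grid_procrustes <- function(a, b, step = 1e-4) {
  ctr <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
  a <- ctr(a); b <- ctr(b)
  thetas <- seq(0, 2 * pi, by = step)
  best <- Inf
  for (th in thetas) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    best <- min(best, sum((b - a %*% t(R))^2))
  }
  sqrt(best)
}

# total Procrustes SS around the consensus (internal helper re-exported
# for test readability)
procrustes_ss_of <- function(g) wingmorph:::procrustes_ss(g)

config_hash_of <- function(cfg) wingmorph:::config_hash(cfg)
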