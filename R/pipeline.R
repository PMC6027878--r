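# tiny FNV-1a hash of a character string (config fingerprint for output
# headers; no cryptographic intent)
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Single configuration object for [run_pipeline()]. Round-trips
#' losslessly through JSON via [write_pipeline_config()] /
#' [read_pipeline_config()] (the simulation block is regenerated from its
#' stored arguments).
#'
#' @param simulation a [sim_config()] (used when `input_tps` is `NULL`).
#' @param input_tps,metadata paths to a TPS file and metadata CSV
#'   (alternative to simulation).
#' @param exclude_ids specimen ids dropped after outlier screening
#'   (explicit manual list; the screen itself never drops).
#' @param sliding semilandmark sliding mode, `"chord"` or `"none"`.
#' @param n_pc retained PC axes for multivariate analyses (default 18).
#' @param n_outlier_axes leading PCs screened per group (default 5).
#' @param n_rand randomized MANOVA replicates (default 1000).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed; mandatory, drives every stochastic step.
#' @param ratio_traits scalar-table columns compared across stages and
#'   genotypes by bootstrap ratios.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            input_tps = NULL, metadata = NULL,
                            exclude_ids = character(),
                            sliding = c("chord", "none"),
                            n_pc = 18L, n_outlier_axes = 5L,
                            n_rand = 1000L, n_boot = 1000L,
                            seed = 1L,
                            ratio_traits = c("area_total", "stlen28")) {
  sliding <- match.arg(sliding)
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(simulation = simulation, input_tps = input_tps,
                 metadata = metadata, exclude_ids = exclude_ids,
                 sliding = sliding, n_pc = as.integer(n_pc),
                 n_outlier_axes = as.integer(n_outlier_axes),
                 n_rand = as.integer(n_rand), n_boot = as.integer(n_boot),
                 seed = as.integer(seed), ratio_traits = ratio_traits),
            class = "pipeline_config")
}

config_hash <- function(config) {
  key <- config[c("input_tps", "metadata", "exclude_ids", "sliding",
                  "n_pc", "n_outlier_axes", "n_rand", "n_boot", "seed",
                  "ratio_traits")]
  key$groups <- if (is.null(config$input_tps)) config$simulation$groups
  fnv1a(as.character(jsonlite::toJSON(key, auto_unbox = TRUE, digits = NA)))
}

#' Run the full analysis pipeline
#'
#' simulate/read -> Procrustes alignment -> semilandmark sliding ->
#' robust outlier screen -> manual exclusions -> re-alignment -> PCA and
#' CVA -> randomization MANOVAs -> trajectory-angle and mean-distance
#' tables -> scalar table -> bootstrap ratio comparisons. Deterministic
#' given the config (and its seed); when `out_dir` is given every table
#' is written as CSV with the config hash in a header comment.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_result` with elements `data`,
#'   `aligned`, `tangent_r`, `outliers`, `excluded`, `pca`, `cva_stage`,
#'   `cva_genotype`, `manova_genotype`, `manova_interaction`,
#'   `trajectory_angles`, `distance_matrix`, `scalars`, `ratios`,
#'   `config`, `hash`, `timings`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  hash <- config_hash(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(what) {
    t1 <- proc.time()[["elapsed"]]
    timings[[what]] <<- t1 - t0
    t0 <<- t1
  }

  stage_fail <- function(stage_name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage_name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  say("ingest")
  dat <- stage_fail("ingest", {
    if (!is.null(config$input_tps))
      read_tps(config$input_tps, config$metadata)
    else generate_dataset(config$simulation, seed = config$seed)
  })
  tick("ingest")

  say("align + slide")
  aligned0 <- stage_fail("align", {
    g <- gpa(dat)
    slide_semilandmarks(g, mode = config$sliding)
  })
  tick("align")

  say("outlier screen")
  outliers <- stage_fail("screen", {
    pc0 <- shape_pca(aligned0, n_axes = max(config$n_outlier_axes,
                                            config$n_outlier_axes))
    grp <- paste(aligned0$info$stage, aligned0$info$genotype, sep = "/")
    mcd_screen(pc0$scores, grp, ids = aligned0$info$id,
               n_axes = config$n_outlier_axes)
  })
  tick("screen")

  excluded <- intersect(config$exclude_ids, dat$info$id)
  kept <- setdiff(dat$info$id, excluded)
  dat_kept <- subset_wings(dat, kept)
  aligned <- if (length(excluded)) {
    stage_fail("realign",
               slide_semilandmarks(gpa(dat_kept), mode = config$sliding))
  } else aligned0
  tangent_r <- tangent_check(aligned)
  tick("realign")

  say("ordination")
  pca <- stage_fail("pca", shape_pca(aligned, n_axes = config$n_pc))
  cva_stage <- stage_fail("cva", cva(pca$scores, aligned$info$stage))
  cva_genotype <- stage_fail("cva", cva(pca$scores, aligned$info$genotype))
  tick("ordination")

  say("randomization MANOVA")
  man_g <- stage_fail("manova", randomized_manova(
    pca$scores, aligned$info$stage, aligned$info$genotype,
    effect = "genotype", n_rand = config$n_rand, seed = config$seed))
  man_i <- stage_fail("manova", randomized_manova(
    pca$scores, aligned$info$stage, aligned$info$genotype,
    effect = "interaction", n_rand = config$n_rand,
    seed = config$seed + 1L))
  tick("manova")

  say("distance tables")
  angles <- stage_fail("tables", trajectory_angles(aligned))
  dmat <- stage_fail("tables", mean_shape_distance_matrix(aligned))
  tick("tables")

  say("scalar measures")
  scal <- stage_fail("scalars", scalar_table(dat_kept))
  ratios <- stage_fail("compare", {
    rows <- list()
    bseed <- config$seed
    for (trait in config$ratio_traits) {
      if (!trait %in% names(scal)) next
      for (gt in unique(scal$genotype)) {
        for (tr in list(c("larva", "pupa"), c("pupa", "adult"),
                        c("larva", "adult"))) {
          num <- scal[scal$genotype == gt & scal$stage == tr[2], trait]
          den <- scal[scal$genotype == gt & scal$stage == tr[1], trait]
          if (!length(num) || !length(den)) next
          bseed <- bseed + 1L
          br <- bootstrap_ratio(num, den, n_boot = config$n_boot,
                                seed = bseed)
          rows[[length(rows) + 1L]] <- data.frame(
            trait = trait, type = "stage", genotype = gt,
            comparison = paste(tr[2], "over", tr[1]),
            ratio = br$point_ratio, ci_lo = br$ci[1], ci_hi = br$ci[2],
            se_boot = br$se_boot, stringsAsFactors = FALSE)
        }
      }
      for (st in unique(scal$stage)) {
        ref <- scal[scal$genotype == "yw" & scal$stage == st, trait]
        if (!length(ref)) next
        for (gt in setdiff(unique(scal$genotype), "yw")) {
          num <- scal[scal$genotype == gt & scal$stage == st, trait]
          if (!length(num)) next
          bseed <- bseed + 1L
          br <- bootstrap_ratio(num, ref, n_boot = config$n_boot,
                                seed = bseed)
          rows[[length(rows) + 1L]] <- data.frame(
            trait = trait, type = "genotype", genotype = gt,
            comparison = paste(gt, "over yw,", st),
            ratio = br$point_ratio, ci_lo = br$ci[1], ci_hi = br$ci[2],
            se_boot = br$se_boot, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  tick("scalars")

  res <- structure(list(
    data = dat, aligned = aligned, tangent_r = tangent_r,
    outliers = outliers, excluded = excluded, pca = pca,
    cva_stage = cva_stage, cva_genotype = cva_genotype,
    manova_genotype = man_g, manova_interaction = man_i,
    trajectory_angles = angles, distance_matrix = dmat,
    scalars = scal, ratios = ratios, config = config, hash = hash,
    timings = timings), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- paste0("config_hash=", hash)
    w <- function(df, name) write_table(df, file.path(out_dir, name), hdr)
    w(cbind(aligned$info,
            as.data.frame(aligned$shapes, optional = TRUE)),
      "aligned_shapes.csv")
    w(data.frame(id = aligned$info$id,
                 centroid_size = aligned$centroid_sizes),
      "centroid_sizes.csv")
    w(as.data.frame(outliers), "outlier_report.csv")
    w(cbind(aligned$info, as.data.frame(pca$scores)), "pca_scores.csv")
    w(cbind(aligned$info, as.data.frame(cva_stage$scores)),
      "cva_stage_scores.csv")
    w(cbind(aligned$info, as.data.frame(cva_genotype$scores)),
      "cva_genotype_scores.csv")
    w(as.data.frame(angles), "trajectory_angles.csv")
    w(data.frame(group = rownames(dmat), as.data.frame(dmat),
                 check.names = FALSE), "mean_shape_distances.csv")
    w(scal, "scalar_table.csv")
    w(ratios, "ratio_comparisons.csv")
    w(data.frame(effect = c("genotype", "stage:genotype"),
                 observed_lambda = c(man_g$observed_lambda,
                                     man_i$observed_lambda),
                 min_null_lambda = c(min(man_g$null_lambdas),
                                     min(man_i$null_lambdas)),
                 p_value = c(man_g$p_value, man_i$p_value),
                 n_rand = config$n_rand),
      "randomization_manova.csv")
    w(data.frame(null_genotype = man_g$null_lambdas,
                 null_interaction = man_i$null_lambdas),
      "null_lambdas.csv")
    log_df <- data.frame(stage = names(timings),
                         seconds = round(unlist(timings), 3))
    w(log_df, "pipeline_log.csv")
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (config", x$hash, "):",
      n_specimens(x$data), "specimens,",
      length(x$excluded), "excluded; tangent r =",
      signif(x$tangent_r, 6), "\n")
  print(x$manova_genotype)
  print(x$manova_interaction)
  invisible(x)
}

#' Write / read a pipeline config as JSON
#'
#' The simulation block is stored as its defining arguments (groups,
#' noise SDs, sex ratio, seed); templates and effect matrices are
#' regenerated from package defaults on read, so the round trip is
#' lossless for default-template configs.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `path` / the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  x <- config[c("input_tps", "metadata", "exclude_ids", "sliding",
                "n_pc", "n_outlier_axes", "n_rand", "n_boot", "seed",
                "ratio_traits")]
  x$simulation <- list(groups = config$simulation$groups,
                       noise_sd = as.list(config$simulation$noise_sd),
                       sex_ratio = config$simulation$sex_ratio,
                       seed = config$simulation$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- sim_config(groups = as.data.frame(x$simulation$groups),
                    noise_sd = unlist(x$simulation$noise_sd),
                    sex_ratio = x$simulation$sex_ratio,
                    seed = x$simulation$seed)
  pipeline_config(simulation = sim,
                  input_tps = x$input_tps, metadata = x$metadata,
                  exclude_ids = as.character(x$exclude_ids %||% character()),
                  sliding = x$sliding, n_pc = x$n_pc,
                  n_outlier_axes = x$n_outlier_axes, n_rand = x$n_rand,
                  n_boot = x$n_boot, seed = x$seed,
                  ratio_traits = as.character(x$ratio_traits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
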