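# End-to-end orchestration of the niche-modelling study design: per
# species, feature building under the sample-size rule, k-fold
# cross-validated fits with mean test AUC, the random-occurrence null
# model, the Boyce index, the small-sample jackknife where applicable, a
# full-data model with its minimum-training-presence threshold; then
# shared-threshold binary ranges, overlap / D / I matrices, shared
# occurrence localities and within-range environmental summaries.

#' Configure a niche-modelling study
#'
#' Exactly one of `scenario` (a [synthetic_scenario], generated on the
#' fly) or `stack_path` + `occurrences_path` (an ESRI-ASCII stack sidecar
#' and an occurrence CSV) must be given.
#'
#' @param scenario a [synthetic_scenario], or `NULL`.
#' @param stack_path path to a stack YAML sidecar (see
#'   [write_raster_stack]), or `NULL`.
#' @param occurrences_path path to an occurrence CSV, or `NULL`.
#' @param folds cross-validation folds (default 10).
#' @param null_replicates random-occurrence null replicates (default 999,
#'   the standard choice; reduce for desk-scale runs — non-default values
#'   are flagged in the report).
#' @param boyce_classes Boyce suitability classes (default 100).
#' @param beta_multiplier global regularization multiplier (default 1).
#' @param jackknife_max_n jackknife is run for species with fewer than
#'   this many records (default 25).
#' @param threshold_mode `"shared"` (species-averaged threshold for the
#'   comparison maps, the default) or `"per_species"`.
#' @param seed global seed; all stage seeds derive from it.
#' @return object of class `study_config`.
#' @export
study_config <- function(scenario = NULL, stack_path = NULL,
                         occurrences_path = NULL, folds = 10L,
                         null_replicates = 999L, boyce_classes = 100L,
                         beta_multiplier = 1, jackknife_max_n = 25L,
                         threshold_mode = c("shared", "per_species"),
                         seed = 1L) {
  if (is.null(scenario) == (is.null(stack_path) || is.null(occurrences_path)))
    stop("give exactly one of `scenario` or `stack_path` + `occurrences_path`")
  structure(list(scenario = scenario, stack_path = stack_path,
                 occurrences_path = occurrences_path,
                 folds = as.integer(folds),
                 null_replicates = as.integer(null_replicates),
                 boyce_classes = as.integer(boyce_classes),
                 beta_multiplier = beta_multiplier,
                 jackknife_max_n = as.integer(jackknife_max_n),
                 threshold_mode = match.arg(threshold_mode),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full niche-modelling study
#'
#' @param config a [study_config].
#' @param quiet suppress progress messages?
#' @return object of class `study_report`: `validation` (one row per
#'   species: n, mean test AUC, null-model 95% CI and verdict, Boyce rho
#'   and p, jackknife D and p where run), `thresholds`, `areas_km2`,
#'   `overlap`, `D`, `I`, `shared_localities`, `env_summaries`,
#'   `surfaces`, `models`, and a `provenance` block with every setting and
#'   seed.  Deterministic given the config.
#' @export
run_study <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(config$scenario)) {
    scen <- config$scenario
    stack <- gen_landscape(scen)
    occ <- list()
    for (i in seq_along(scen$species)) {
      nm <- names(scen$species)[i]
      sp <- scen$species[[i]]
      tr <- true_suitability(stack, sp$coefficients, sp$intercept)
      occ[[nm]] <- sample_occurrences(tr, sp$n, seed = scen$seed + i,
                                      species = nm)
    }
  } else {
    stack <- read_raster_stack(config$stack_path)
    occ <- read_occurrences(config$occurrences_path, stack)
  }

  species <- names(occ)
  models <- list(); surfaces <- list(); thresholds <- numeric()
  rows <- list()
  for (si in seq_along(species)) {
    nm <- species[si]
    o <- occ[[nm]]
    n <- length(o)
    sp_seed <- config$seed + 1000L * si
    say("[%s] n = %d: fitting (features: %s)", nm, n,
        paste(feature_classes_for_n(n), collapse = "+"))
    features <- build_features(stack, sample_size = n, seed = sp_seed)

    full <- maxent(features, o, beta_multiplier = config$beta_multiplier)
    surf <- predict(full, type = "logistic")
    thr <- mtp_threshold(full)
    cv <- crossvalidate(features, o, k = config$folds, seed = sp_seed,
                        beta_multiplier = config$beta_multiplier)
    say("[%s] mean test AUC %.3f; null model (%d replicates)...",
        nm, cv$mean_test_auc, config$null_replicates)
    nullr <- null_model_test(features, o,
                             replicates = config$null_replicates,
                             seed = sp_seed + 1L,
                             beta_multiplier = config$beta_multiplier)
    boyce <- boyce_index(surf, o, classes = config$boyce_classes)
    jk <- NULL
    if (n < config$jackknife_max_n) {
      say("[%s] jackknife validation (n = %d < %d)...", nm, n,
          config$jackknife_max_n)
      jk <- jackknife_small_sample(stack, o, seed = sp_seed + 2L,
                                   beta_multiplier = config$beta_multiplier)
    }
    models[[nm]] <- full
    surfaces[[nm]] <- surf
    thresholds[nm] <- thr
    rows[[nm]] <- data.frame(
      species = nm, n = n,
      mean_test_auc = cv$mean_test_auc,
      training_auc = nullr$real_auc,
      null_ci95 = nullr$ci95,
      null_significant = nullr$significant,
      boyce_rho = boyce$rho, boyce_p = boyce$p_value,
      jackknife_D = if (is.null(jk)) NA_real_ else jk$D,
      jackknife_p = if (is.null(jk)) NA_real_ else jk$p_value,
      mtp_threshold = thr)
  }

  thr_shared <- shared_threshold(thresholds)
  ranges <- lapply(species, function(nm)
    binarize(surfaces[[nm]],
             if (config$threshold_mode == "shared") thr_shared
             else thresholds[nm],
             cellsize = stack$cellsize))
  names(ranges) <- species
  sim <- similarity_matrices(surfaces)
  report <- structure(list(
    validation = do.call(rbind, rows),
    thresholds = thresholds, shared_threshold = thr_shared,
    areas_km2 = vapply(ranges, `[[`, numeric(1), "area_km2"),
    overlap = overlap_matrix(ranges),
    D = sim$D, I = sim$I,
    shared_localities = shared_occurrence_localities(occ),
    env_summaries = lapply(ranges, function(r) env_summary(stack, r)),
    ranges = ranges, surfaces = surfaces, models = models,
    occurrences = occ, stack = stack,
    provenance = list(
      seed = config$seed, folds = config$folds,
      null_replicates = config$null_replicates,
      null_replicates_default = config$null_replicates == 999L,
      boyce_classes = config$boyce_classes,
      beta_multiplier = config$beta_multiplier,
      jackknife_max_n = config$jackknife_max_n,
      threshold_mode = config$threshold_mode,
      package_version = as.character(utils::packageVersion("nichemax")))),
    class = "study_report")
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("niche-modelling study report\n")
  if (!x$provenance$null_replicates_default)
    cat(sprintf("  NOTE: non-default null replicates (%d, default 999)\n",
                x$provenance$null_replicates))
  cat(sprintf("  shared threshold: %.4f\n", x$shared_threshold))
  print(x$validation[, c("species", "n", "mean_test_auc", "null_ci95",
                         "null_significant", "boyce_rho", "boyce_p",
                         "jackknife_p", "mtp_threshold")],
        row.names = FALSE, digits = 4)
  cat("\nSchoener's D:\n"); print(round(x$D, 3))
  cat("\nrange overlap:\n"); print(round(x$overlap, 3))
  cat("\npredicted areas (km2):\n"); print(round(x$areas_km2, 2))
  invisible(x)
}

#' Write a study report to disk
#'
#' JSON (validation table, matrices, thresholds, areas, provenance) plus
#' CSV tables and per-species logistic suitability grids as ESRI ASCII.
#'
#' @param report a [run_study] report.
#' @param dir output directory.
#' @param write_surfaces also write the suitability grids?
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir, write_surfaces = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(validation = report$validation,
         thresholds = as.list(report$thresholds),
         shared_threshold = report$shared_threshold,
         areas_km2 = as.list(report$areas_km2),
         overlap = report$overlap, D = report$D, I = report$I,
         shared_localities = report$shared_localities,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$validation, file.path(dir, "validation.csv"),
                   row.names = FALSE)
  for (nm in c("overlap", "D", "I", "shared_localities"))
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")))
  env <- do.call(rbind, lapply(names(report$env_summaries), function(nm)
    cbind(species = nm, report$env_summaries[[nm]])))
  utils::write.csv(env, file.path(dir, "env_summaries.csv"),
                   row.names = FALSE)
  if (write_surfaces) {
    st <- report$stack
    for (nm in names(report$surfaces))
      write_ascii_grid(report$surfaces[[nm]],
                       file.path(dir, paste0("suitability_", nm, ".asc")),
                       st$xll, st$yll, st$cellsize)
  }
  invisible(dir)
}
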