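#' Fit a presence-only maximum-entropy niche model
#'
#' Fits the maxent habitat-suitability model: the probability distribution
#' over background cells that is closest to uniform subject to (softly)
#' matching the presence feature means — equivalently, the Gibbs density
#' `exp(lambda . f(x)) / Z` whose weights minimize the L1-regularized
#' negative presence log-likelihood
#' \deqn{J(\lambda) = -\frac{1}{m}\sum_{presences} \lambda\cdot f(x_i)
#'   + \log Z(\lambda) + \sum_j \beta_j |\lambda_j|.}
#' Regularization follows the classic maxent defaults:
#' `beta_j = class_default(m) * beta_multiplier * sd_presence(f_j) / sqrt(m)`
#' with the per-class default tables interpolated in the sample size `m`
#' and the presence standard deviation floored at 0.05.
#' Optimization is coordinate-wise proximal-Newton descent with soft
#' thresholding, run to a relative objective change below `tol`.
#'
#' @param x a [raster_stack] (features are then built with
#'   [build_features] under the sample-size rule) or a prebuilt
#'   [build_features] object.
#' @param presences an [occurrence_set]; every presence must fall on a
#'   background cell.
#' @param beta_multiplier global multiplier on the default regularization
#'   (1 = defaults; 0 = exact constraint matching).
#' @param tol relative objective-change convergence tolerance.
#' @param maxit maximum full coordinate sweeps.
#' @param seed seed (used only when the background is subsampled).
#' @param ... passed to [build_features] when `x` is a stack.
#'
#' @return An object of class `maxent`: feature weights `lambda` (named by
#'   descriptor), per-feature `beta`, `logZ`, the entropy `H` of the fitted
#'   raw distribution, the fitted `raw` probabilities over background
#'   (summing to 1), presence cell ids, convergence diagnostics, and the
#'   `features` used.
#' @seealso [predict.maxent], [mtp_threshold], [crossvalidate]
#' @examples
#' scen <- gradient_study_scenario(seed = 1, n_rows = 40, n_cols = 40,
#'                                 n = c(30L, 25L, 20L, 12L))
#' m <- maxent(scen$stack, scen$occurrences$species_a)
#' summary(m)
#' @export
maxent <- function(x, presences, beta_multiplier = 1, tol = 1e-9,
                   maxit = 500L, seed = 1L, ...) {
  features <- if (inherits(x, "maxent_features")) x
              else build_features(x, sample_size = length(presences),
                                  seed = seed, ...)
  pidx <- presence_rows(features, presences)
  fit_maxent_rows(features, pidx, beta_multiplier = beta_multiplier,
                  tol = tol, maxit = maxit, seed = seed,
                  species = presences$species)
}

presence_rows <- function(features, presences) {
  ids <- occ_cell_ids(presences, features$stack)
  pidx <- match(ids, features$cells)
  if (anyNA(pidx))
    stop(sprintf("%d presence cell(s) of '%s' are not background cells",
                 sum(is.na(pidx)), presences$species))
  pidx
}

# core fit given presence row indices into the background; `beta` overrides
# the default per-feature regularization when supplied
fit_maxent_rows <- function(features, pidx, beta_multiplier = 1, tol = 1e-9,
                            maxit = 500L, seed = 1L, species = "unknown",
                            beta = NULL) {
  m <- length(pidx)
  if (m < 2) stop("need at least 2 presences")
  F <- features$F
  pmean <- if (ncol(F)) colMeans(F[pidx, , drop = FALSE]) else numeric(0)
  # beta_j = class_default(m) * multiplier * sd_presence(f_j) / sqrt(m),
  # the classic maxent default; presence sd floored so that features
  # constant over the presences keep a positive penalty
  if (is.null(beta)) beta <- if (ncol(F)) {
    psd <- sqrt(pmax(colMeans(F[pidx, , drop = FALSE]^2) - pmean^2, 0) *
                  m / max(m - 1, 1))
    vapply(seq_len(ncol(F)), function(j)
      default_class_beta(features$descriptors$class[j], m), numeric(1)) *
      beta_multiplier * pmax(psd, 0.05) / sqrt(m)
  } else numeric(0) else beta <- rep_len(beta, ncol(F))

  fit <- maxent_cd(F, pmean, beta, tol = tol, maxit = as.integer(maxit))
  if (!fit$converged)
    warning(sprintf("maxent fit for '%s' did not converge in %d sweeps (objective %.8g)",
                    species, maxit, fit$objective))
  raw <- as.numeric(fit$raw)
  H <- -sum(raw * log(raw))
  lambda <- as.numeric(fit$lambda)
  names(lambda) <- feature_labels(features$descriptors)
  structure(list(lambda = lambda, beta = beta,
                 beta_multiplier = beta_multiplier,
                 logZ = fit$logZ, H = H, raw = raw,
                 presence_rows = pidx,
                 presence_cells = features$cells[pidx],
                 species = species, objective = fit$objective,
                 iterations = fit$iterations, converged = fit$converged,
                 features = features, seed = seed),
            class = "maxent")
}

feature_labels <- function(d) {
  ifelse(d$class %in% c("linear", "quadratic"),
         paste(d$layer, d$class, sep = "."),
         ifelse(d$class == "category",
                sprintf("%s.cat%g", d$layer, d$param),
                sprintf("%s.%s@%.4g", d$layer, d$class, d$param)))
}

#' @export
print.maxent <- function(x, ...) {
  cat(sprintf("maxent niche model for '%s'\n", x$species))
  cat(sprintf("  %d presences, %d background cells, %d features (%d active)\n",
              length(x$presence_rows), length(x$raw), length(x$lambda),
              sum(x$lambda != 0)))
  cat(sprintf("  beta multiplier %g, entropy H = %.4f, converged: %s (%d sweeps)\n",
              x$beta_multiplier, x$H, x$converged, x$iterations))
  invisible(x)
}

#' @export
summary.maxent <- function(object, ...) {
  act <- object$lambda[object$lambda != 0]
  s <- list(species = object$species,
            n_presence = length(object$presence_rows),
            n_background = length(object$raw),
            n_features = length(object$lambda),
            n_active = length(act),
            top_weights = sort(abs(act), decreasing = TRUE)[seq_len(min(10, length(act)))],
            entropy = object$H, logZ = object$logZ,
            objective = object$objective, converged = object$converged)
  class(s) <- "summary.maxent"
  s
}

#' @export
print.summary.maxent <- function(x, ...) {
  cat(sprintf("maxent model: '%s' (%d presences over %d background cells)\n",
              x$species, x$n_presence, x$n_background))
  cat(sprintf("  features: %d (%d with nonzero weight); entropy %.4f; converged %s\n",
              x$n_features, x$n_active, x$entropy, x$converged))
  if (length(x$top_weights)) {
    cat("  largest |weights|:\n")
    for (nm in names(x$top_weights))
      cat(sprintf("    %-28s %8.4f\n", nm, x$top_weights[[nm]]))
  }
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$lambda

#' Predict suitability surfaces from a fitted maxent model
#'
#' `type = "raw"` gives the fitted Gibbs probabilities
#' `exp(lambda . f - logZ)`, which sum to 1 over background cells.
#' `type = "logistic"` applies the entropy-calibrated logistic transform
#' `e^H raw / (1 + e^H raw)`, a strictly increasing map into (0,1) whose
#' value is 0.5 at cells of "typical" presence suitability.
#'
#' @param object a fitted [maxent] model.
#' @param features a [build_features] expansion with the same descriptors;
#'   defaults to the training features.
#' @param type `"logistic"` (default) or `"raw"`.
#' @param as_surface return a grid matrix (`TRUE`, default) or a vector
#'   over background cells.
#' @param ... unused.
#' @return matrix on the stack grid (NA off background) or numeric vector.
#' @export
predict.maxent <- function(object, features = NULL, type = c("logistic", "raw"),
                           as_surface = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(features)) {
    raw <- object$raw
    features <- object$features
  } else {
    if (!identical(features$descriptors[c("layer", "class")],
                   object$features$descriptors[c("layer", "class")]))
      stop("feature descriptors do not match the fitted model")
    eta <- as.numeric(features$F %*% object$lambda)
    # renormalize over the prediction background so raw sums to 1 there
    # (equals exp(eta - logZ) on the training background)
    mx <- max(eta)
    raw <- exp(eta - mx - log(sum(exp(eta - mx))))
  }
  out <- if (type == "raw") raw else {
    eH <- exp(object$H)
    eH * raw / (1 + eH * raw)
  }
  if (as_surface) vector_to_surface(out, features) else out
}

#' @export
plot.maxent <- function(x, type = "logistic", ...) {
  s <- predict(x, type = type)
  graphics::image(t(s[nrow(s):1, ]), useRaster = TRUE, axes = FALSE,
                  main = sprintf("%s suitability: %s", type, x$species),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Minimum-training-presence threshold
#'
#' The lowest predicted (logistic) suitability over the training
#' presences.  Binarizing the map at `>= threshold` keeps every training
#' presence inside the predicted range, i.e. zero omission of training
#' data.
#'
#' @param model a fitted [maxent] model, or a logistic surface matrix.
#' @param presences an [occurrence_set]; defaults to the model's training
#'   presences.
#' @return the threshold, in (0,1).
#' @export
mtp_threshold <- function(model, presences = NULL) {
  if (inherits(model, "maxent")) {
    surf <- predict(model, type = "logistic", as_surface = FALSE)
    rows <- if (is.null(presences)) model$presence_rows
            else presence_rows(model$features, presences)
    return(min(surf[rows]))
  }
  if (is.null(presences)) stop("presences required when passing a surface")
  min(model[cbind(presences$row, presences$col)], na.rm = TRUE)
}

#' k-fold cross-validation of a maxent model
#'
#' Randomly partitions the presence records into `k` near-equal folds
#' (sizes differ by at most one), fits one model per fold on the other
#' `k - 1` folds, and records the held-out cells for evaluation.  The
#' replicate test AUCs (held-out presence scores against all background
#' scores) summarize predictive discrimination.
#'
#' @param x a [raster_stack] or [build_features] expansion.
#' @param presences an [occurrence_set] with at least 2 records; if fewer
#'   than `k`, `k` is reduced to `n` (leave-one-out) with a warning.
#' @param k number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @param beta_multiplier,... passed to the per-fold fits.
#' @return object of class `cv_maxent`: `folds` (fold id per presence),
#'   `models`, `test_rows`, and `test_auc` per replicate with its mean.
#' @export
crossvalidate <- function(x, presences, k = 10L, seed = 1L,
                          beta_multiplier = 1, ...) {
  n <- length(presences)
  if (n < 2) stop("need at least 2 presences to cross-validate")
  if (n < k) {
    warning(sprintf("only %d presences: reducing folds from %d to %d (leave-one-out)",
                    n, k, n))
    k <- n
  }
  features <- if (inherits(x, "maxent_features")) x
              else build_features(x, sample_size = n, seed = seed, ...)
  pidx <- presence_rows(features, presences)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  models <- vector("list", k)
  test_rows <- vector("list", k)
  test_auc <- numeric(k)
  for (f in seq_len(k)) {
    train <- pidx[fold != f]
    test <- pidx[fold == f]
    models[[f]] <- fit_maxent_rows(features, train,
                                   beta_multiplier = beta_multiplier,
                                   species = presences$species)
    test_rows[[f]] <- test
    scores <- models[[f]]$raw
    test_auc[f] <- auc_presence_background(scores[test], scores)$auc
  }
  structure(list(folds = fold, models = models, test_rows = test_rows,
                 test_auc = test_auc, mean_test_auc = mean(test_auc),
                 k = k, seed = seed, species = presences$species),
            class = "cv_maxent")
}

#' @export
print.cv_maxent <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of '%s': mean test AUC %.4f (replicates %s)\n",
              x$k, x$species, x$mean_test_auc,
              paste(sprintf("%.3f", x$test_auc), collapse = ", ")))
  invisible(x)
}

# ---- model serialization ---------------------------------------------------

#' Write a fitted maxent model as JSON
#'
#' Serializes weights, descriptors, regularization, normalizer, entropy
#' and settings (not the feature matrix; rebuild it from the stack with
#' [build_features] to predict).
#'
#' @param model a [maxent] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maxent_json <- function(model, path) {
  obj <- list(species = model$species,
              descriptors = model$features$descriptors,
              lambda = unname(model$lambda), beta = model$beta,
              beta_multiplier = model$beta_multiplier,
              logZ = model$logZ, H = model$H,
              presence_cells = model$presence_cells,
              classes = model$features$classes,
              hinge_knots = model$features$hinge_knots,
              seed = model$seed, objective = model$objective,
              converged = model$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a maxent model written by [write_maxent_json]
#'
#' @param path JSON path.
#' @param stack the [raster_stack] the model was fitted on (features are
#'   rebuilt from it).
#' @return a [maxent] model.
#' @export
read_maxent_json <- function(path, stack) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  features <- build_features(stack, sample_size = length(obj$presence_cells),
                             hinge_knots = obj$hinge_knots,
                             feature_classes = obj$classes)
  eta <- as.numeric(features$F %*% obj$lambda)
  raw <- exp(eta - obj$logZ)
  lambda <- obj$lambda
  names(lambda) <- feature_labels(features$descriptors)
  structure(list(lambda = lambda, beta = obj$beta,
                 beta_multiplier = obj$beta_multiplier,
                 logZ = obj$logZ, H = obj$H, raw = raw,
                 presence_rows = match(obj$presence_cells, features$cells),
                 presence_cells = obj$presence_cells,
                 species = obj$species, objective = obj$objective,
                 iterations = NA_integer_, converged = obj$converged,
                 features = features, seed = obj$seed),
            class = "maxent")
}
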