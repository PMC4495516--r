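# Model validation: presence-background AUC, the random-occurrence null
# model, the continuous Boyce index, and the small-sample leave-one-out
# jackknife.

#' Presence-background AUC
#'
#' The probability that the model scores a presence point higher than a
#' random background point, computed exactly as the Mann-Whitney rank-sum
#' statistic with ties counted 1/2 (midranks).  Invariant under any
#' strictly monotone transform of the scores, so raw and logistic surfaces
#' give the same AUC.
#'
#' With presence-background data the achievable ceiling is below 1 by half
#' the (unknowable) fraction of background actually occupied; the value is
#' reported as computed, without any such correction.
#'
#' @param presence_scores,background_scores non-empty numeric vectors of
#'   model scores.
#' @return object of class `auc_result`: `auc`, `n_presence`,
#'   `n_background`.
#' @export
auc_presence_background <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0L || nb == 0L)
    stop("presence and background score vectors must be non-empty")
  r <- rank(c(presence_scores, background_scores))  # midranks for ties
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
  structure(list(auc = auc, n_presence = np, n_background = nb),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d presence vs %d background scores)\n",
              x$auc, x$n_presence, x$n_background))
  invisible(x)
}

#' Random-occurrence null-model significance test
#'
#' Tests whether a species' model discriminates better than models fitted
#' to randomly placed occurrences: `replicates` sets of `n` cells are
#' drawn uniformly without replacement from the background, a model with
#' identical settings is fitted to each, and its training AUC recorded.
#' The species' model is significant when its AUC reaches the empirical
#' 95th percentile of the null AUCs (rank `ceiling(0.95 * (R + 1))` of the
#' sorted list).
#'
#' By default the species' own *training* AUC is compared to the null
#' training AUCs (like with like).  Passing `real_auc` (e.g. a
#' cross-validated mean test AUC) compares that value instead — the
#' mixed test-vs-training comparison some studies report.
#'
#' @param features a [build_features] expansion (identical settings are
#'   reused for every null fit).
#' @param occurrences the species' [occurrence_set]; its size sets `n`.
#' @param replicates number of null replicates (default 999; >= 19).
#' @param seed seed for the null draws.
#' @param beta_multiplier passed to the fits.
#' @param real_auc optional externally computed AUC to test instead of the
#'   training AUC.
#' @return object of class `null_model_result`: `null_aucs`, `real_auc`,
#'   `ci95` (the rank-rule percentile), `significant`, `mode`.
#' @export
null_model_test <- function(features, occurrences, replicates = 999L,
                            seed = 1L, beta_multiplier = 1,
                            real_auc = NULL) {
  if (replicates < 19L) stop("need at least 19 null replicates")
  n <- length(occurrences)
  N <- nrow(features$F)
  if (n > N) stop("more occurrences than background cells")
  mode <- if (is.null(real_auc)) "training-vs-training" else "supplied-vs-training"
  if (is.null(real_auc)) {
    real <- maxent(features, occurrences, beta_multiplier = beta_multiplier)
    real_auc <- auc_presence_background(real$raw[real$presence_rows],
                                        real$raw)$auc
  }
  null_aucs <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      rows <- sample.int(N, n)
      fit <- fit_maxent_rows(features, rows,
                             beta_multiplier = beta_multiplier,
                             species = sprintf("null_%d", r))
      auc_presence_background(fit$raw[rows], fit$raw)$auc
    }, numeric(1))
  })
  ci95 <- sort(null_aucs)[min(replicates, ceiling(0.95 * (replicates + 1)))]
  structure(list(null_aucs = null_aucs, real_auc = real_auc, ci95 = ci95,
                 significant = real_auc >= ci95, replicates = replicates,
                 n = n, mode = mode, seed = seed),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("null model (%d replicates of n = %d, %s): real AUC %.4f vs null 95%% CI %.4f -> %s\n",
              x$replicates, x$n, x$mode, x$real_auc, x$ci95,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Continuous Boyce index
#'
#' Partitions the logistic suitability scale [0,1] into `classes`
#' equal-interval bins.  Per bin, the Predicted frequency is the share of
#' occurrence points whose suitability falls in the bin and the Expected
#' frequency the share of valid grid cells.  A model whose suitability
#' tracks occurrence density shows a Predicted-to-Expected (P/E) ratio
#' increasing with suitability; the index is the Spearman rank correlation
#' of P/E against class rank over bins with nonzero Expected frequency,
#' with a one-tailed (positive association) p-value — exact when at most
#' 10 usable classes, t-approximate otherwise.
#'
#' @param surface logistic suitability matrix (values in [0,1], NA =
#'   nodata).
#' @param occurrences an [occurrence_set] on the same grid.
#' @param classes number of suitability classes (default 100, >= 2).
#' @return object of class `boyce_result`: `table` (per-class bounds,
#'   predicted, expected, `pe`), `rho`, `p_value`, `classes`.
#' @export
boyce_index <- function(surface, occurrences, classes = 100L) {
  if (classes < 2L) stop("need at least 2 classes")
  occ_scores <- surface[cbind(occurrences$row, occurrences$col)]
  occ_scores <- occ_scores[!is.na(occ_scores)]
  if (length(occ_scores) == 0L)
    stop("all occurrences fall on nodata cells")
  cells <- surface[!is.na(surface)]
  bin <- function(v) pmin(floor(v * classes) + 1L, classes)
  expected <- tabulate(bin(cells), nbins = classes) / length(cells)
  predicted <- tabulate(bin(occ_scores), nbins = classes) / length(occ_scores)
  usable <- expected > 0
  pe <- predicted[usable] / expected[usable]
  rank_ <- seq_len(classes)[usable]
  ct <- suppressWarnings(
    stats::cor.test(rank_, pe, method = "spearman",
                    alternative = "greater", exact = sum(usable) <= 10))
  structure(list(table = data.frame(class = seq_len(classes),
                                    lower = (seq_len(classes) - 1) / classes,
                                    upper = seq_len(classes) / classes,
                                    predicted = predicted, expected = expected,
                                    pe = ifelse(expected > 0,
                                                predicted / expected, NA_real_)),
                 rho = unname(ct$estimate), p_value = ct$p.value,
                 n_usable = sum(usable), classes = classes),
            class = "boyce_result")
}

#' @export
print.boyce_result <- function(x, ...) {
  cat(sprintf("Boyce index: rho = %.4f over %d/%d usable classes, one-tailed p = %.4g\n",
              x$rho, x$n_usable, x$classes, x$p_value))
  invisible(x)
}

#' Small-sample leave-one-out jackknife validation
#'
#' For presence samples with `n < 25`, fits `n` models each leaving one
#' record out.  For replicate `i`, the success flag `X_i` is 1 when the
#' left-out point's logistic suitability reaches that replicate's
#' minimum-training-presence threshold, and `P_i` is the proportion of
#' background cells at or above the threshold (the chance of success under
#' random placement).  The test statistic is `D = sum X_i (1 - P_i)`; its
#' p-value is the probability under independent Bernoulli(`P_i`) successes
#' that `D` is at least the observed value — by exact enumeration of all
#' `2^n` outcomes for `n <= 20`, else by seeded Monte Carlo.
#'
#' @param x a [raster_stack] or [build_features] expansion.
#' @param occurrences an [occurrence_set] with `2 <= n < 25`.
#' @param seed seed for the Monte Carlo p-value (only used when `n > 20`).
#' @param beta_multiplier passed to the fits.
#' @param mc_draws Monte Carlo sample size for `n > 20`.
#' @return object of class `jackknife_result`: `X`, `P`, `D`, `p_value`,
#'   `method`.
#' @export
jackknife_small_sample <- function(x, occurrences, seed = 1L,
                                   beta_multiplier = 1, mc_draws = 1e6) {
  n <- length(occurrences)
  if (n >= 25)
    stop("jackknife validation targets samples with n < 25; use crossvalidate() for larger samples")
  if (n < 2) stop("need at least 2 occurrences")
  features <- if (inherits(x, "maxent_features")) x
              else build_features(x, sample_size = n - 1L)
  pidx <- presence_rows(features, occurrences)
  X <- integer(n); P <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_maxent_rows(features, pidx[-i],
                           beta_multiplier = beta_multiplier,
                           species = occurrences$species)
    logi <- predict(fit, type = "logistic", as_surface = FALSE)
    thr <- min(logi[pidx[-i]])
    X[i] <- as.integer(logi[pidx[i]] >= thr - 1e-12)
    P[i] <- mean(logi >= thr - 1e-12)
  }
  D <- jackknife_statistic(X, P)
  pv <- jackknife_pvalue(D, P, seed = seed, mc_draws = mc_draws)
  structure(c(list(X = X, P = P, D = D), pv,
              list(species = occurrences$species)),
            class = "jackknife_result")
}

#' Jackknife test statistic and null p-value
#'
#' `jackknife_statistic` evaluates `D = sum X_i (1 - P_i)`.
#' `jackknife_pvalue` computes `P(D_null >= D)` where each replicate
#' succeeds independently with probability `P_i` — exactly (enumeration
#' via convolution of the `2^n` outcome distribution) for `n <= 20`, by
#' seeded Monte Carlo above.
#'
#' @param X 0/1 success flags.
#' @param P per-replicate success probabilities in [0,1].
#' @param D observed statistic.
#' @param seed,mc_draws Monte Carlo controls for `n > 20`.
#' @return `jackknife_statistic`: the statistic. `jackknife_pvalue`: list
#'   with `p_value` and `method` (`"exact"` or `"monte-carlo"`).
#' @export
jackknife_statistic <- function(X, P) {
  stopifnot(length(X) == length(P), all(X %in% c(0, 1)),
            all(P >= 0 & P <= 1))
  sum(X * (1 - P))
}

#' @rdname jackknife_statistic
#' @export
jackknife_pvalue <- function(D, P, seed = 1L, mc_draws = 1e6) {
  n <- length(P)
  if (n <= 20L) {
    vals <- 0; prob <- 1
    for (i in seq_len(n)) {
      vals <- c(vals, vals + (1 - P[i]))
      prob <- c(prob * (1 - P[i]), prob * P[i])
    }
    list(p_value = sum(prob[vals >= D - 1e-9]), method = "exact")
  } else {
    p <- with_seed(seed, {
      Dnull <- numeric(mc_draws)
      for (i in seq_len(n))
        Dnull <- Dnull + (stats::runif(mc_draws) < P[i]) * (1 - P[i])
      mean(Dnull >= D - 1e-9)
    })
    list(p_value = p, method = "monte-carlo")
  }
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("jackknife validation of '%s' (n = %d): %d/%d successes, D = %.4f, p = %.4g (%s)\n",
              x$species, length(x$X), sum(x$X), length(x$X), x$D, x$p_value,
              x$method))
  invisible(x)
}
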