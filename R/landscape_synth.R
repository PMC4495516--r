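# Synthetic landscapes: spatially autocorrelated environmental gradients,
# a categorical cover layer, derived terrain layers, and presence-only
# samples drawn from known species response curves.  These emulate the
# statistical structure the niche analysis assumes (gradient + spatially
# correlated noise + small presence samples), not any real geography.

# evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Stationary Gaussian random field by FFT convolution of white noise with a
# Gaussian kernel on a grid padded by one correlation length per edge (the
# periodic wrap is trimmed away).  `corr_length` (cells) is the lag at which
# correlation falls to 1/e; unit marginal variance before scaling.
gaussian_random_field <- function(n_rows, n_cols, corr_length) {
  stopifnot(corr_length > 0)
  pad <- ceiling(corr_length)
  nr <- n_rows + 2L * pad
  nc <- n_cols + 2L * pad
  sigma <- corr_length / 2           # kernel sd; correlogram exp(-d^2/(4 sigma^2))
  di <- pmin(seq_len(nr) - 1L, nr - (seq_len(nr) - 1L))
  dj <- pmin(seq_len(nc) - 1L, nc - (seq_len(nc) - 1L))
  k <- exp(-outer(di^2, dj^2, `+`) / (2 * sigma^2))
  k <- k / sqrt(sum(k^2))            # unit variance after convolution
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  f[pad + seq_len(n_rows), pad + seq_len(n_cols)]
}

#' Define a synthetic landscape scenario
#'
#' A scenario is a recipe for [gen_landscape]: grid geometry, continuous
#' layers built as deterministic linear trends plus Gaussian-random-field
#' noise with a stated correlation length, one categorical cover layer from
#' a thresholded latent field, derived slope and distance layers, and the
#' per-species generating response curves and sample sizes used by
#' [true_suitability] and [sample_occurrences].
#'
#' @param n_rows,n_cols grid size in cells.
#' @param cellsize cell size in meters.
#' @param layers list of continuous-layer recipes; each a list with `name`,
#'   `base` (value at grid center), `gradient_x`,`gradient_y` (total change
#'   across the grid along x / y, natural units), `corr_length` (cells, > 0)
#'   and `sd` (random-field standard deviation, natural units; 0 = pure
#'   trend).
#' @param categorical recipe for the cover layer: list with `name`,
#'   `n_classes`, `corr_length`; `NULL` to omit.
#' @param slope_from name of the layer to derive a slope layer from
#'   (`NULL` to skip).
#' @param distance_layers list of recipes, each `list(name=, n_sources=)`:
#'   sources are drawn uniformly over the grid and the Euclidean
#'   distance-to-nearest-source layer appended.
#' @param species named list of generating responses, each a list with
#'   `intercept` and `coefficients` (named list per layer of
#'   `c(linear, quadratic)` on the z-scored layer) plus `n` (sample size).
#' @param seed integer seed recorded in the scenario and used for all of
#'   its randomness.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_rows, n_cols, cellsize = 90,
                               layers, categorical = NULL,
                               slope_from = NULL, distance_layers = list(),
                               species = list(), seed = 1L) {
  for (l in layers) {
    if (is.null(l$name)) stop("every layer recipe needs a name")
    if (!is.null(l$corr_length) && l$corr_length <= 0)
      stop("correlation lengths must be > 0")
  }
  for (sp in species)
    if (!is.null(sp$n) && sp$n < 1) stop("sample sizes must be >= 1")
  structure(list(n_rows = n_rows, n_cols = n_cols, cellsize = cellsize,
                 layers = layers, categorical = categorical,
                 slope_from = slope_from, distance_layers = distance_layers,
                 species = species, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Read a scenario from YAML
#' @param path YAML file with the fields of [synthetic_scenario].
#' @return a `synthetic_scenario`.
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 resolves a bare `n` key as boolean; map it back
  y$species <- lapply(y$species, function(sp) {
    names(sp)[names(sp) %in% c("FALSE", "no")] <- "n"
    sp
  })
  do.call(synthetic_scenario, y)
}

#' Generate the environmental stack of a scenario
#'
#' Continuous layers are a deterministic linear trend across the grid plus
#' a Gaussian random field of the stated correlation length and standard
#' deviation (spectral/convolution synthesis from the scenario seed).  The
#' categorical layer discretizes a latent field into equiprobable classes.
#' Slope and distance layers are appended through the geodata operations,
#' so derived layers are exactly what the pipeline would compute on real
#' inputs.
#'
#' @param scenario a [synthetic_scenario].
#' @return a [raster_stack]; bit-identical for the same scenario and seed.
#' @export
gen_landscape <- function(scenario) {
  with_seed(scenario$seed, {
    nr <- scenario$n_rows; nc <- scenario$n_cols
    gx <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE) - 0.5
    gy <- matrix(seq(0, 1, length.out = nr), nr, nc) - 0.5  # row 1 = north
    layers <- list(); kinds <- character()
    for (l in scenario$layers) {
      trend <- l$base + (l$gradient_x %||% 0) * gx + (l$gradient_y %||% 0) * gy
      sdv <- l$sd %||% 0
      vals <- if (sdv > 0)
        trend + sdv * gaussian_random_field(nr, nc, l$corr_length %||% 10)
      else trend
      layers[[l$name]] <- vals
      kinds[l$name] <- "continuous"
    }
    if (!is.null(scenario$categorical)) {
      cc <- scenario$categorical
      latent <- gaussian_random_field(nr, nc, cc$corr_length %||% 8)
      br <- stats::quantile(latent, probs = seq(0, 1, length.out = cc$n_classes + 1L))
      br[1L] <- -Inf; br[length(br)] <- Inf
      layers[[cc$name]] <- matrix(as.numeric(cut(latent, br, labels = FALSE)),
                                  nr, nc)
      kinds[cc$name] <- "categorical"
    }
    stk <- raster_stack(layers, kinds = kinds, xll = 0, yll = 0,
                        cellsize = scenario$cellsize, crs = "synthetic")
    if (!is.null(scenario$slope_from))
      stk <- slope_from_elevation(stk, scenario$slope_from, name = "slope")
    for (dl in scenario$distance_layers) {
      src <- matrix(FALSE, nr, nc)
      src[sample.int(nr * nc, dl$n_sources)] <- TRUE
      stk <- euclidean_distance_layer(stk, src, name = dl$name)
    }
    stk
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth suitability from a generating response curve
#'
#' Suitability is the inverse logit of a quadratic polynomial in z-scored
#' layer values: `logit(s) = b0 + sum_l (b1_l z_l + b2_l z_l^2)`.
#' Standardization (mean/sd over valid cells) happens here, so stored
#' layers keep natural units.
#'
#' @param stack a [raster_stack].
#' @param coefficients named list, one entry per continuous layer used:
#'   numeric length-2 `c(linear, quadratic)`.
#' @param intercept the polynomial's intercept `b0`.
#' @return object of class `true_suitability`: `surface` matrix in [0,1]
#'   (NA off-mask), plus the generating coefficients and the grid.
#' @export
true_suitability <- function(stack, coefficients, intercept = 0) {
  eta <- matrix(intercept, n_rows(stack), n_cols(stack))
  for (nm in names(coefficients)) {
    if (!nm %in% names(stack$layers))
      stop(sprintf("no layer '%s' in the stack", nm))
    if (stack$kinds[[nm]] != "continuous")
      stop(sprintf("layer '%s' is categorical", nm))
    v <- stack$layers[[nm]]
    mu <- mean(v[stack$mask]); sdv <- stats::sd(v[stack$mask])
    z <- (v - mu) / if (sdv > 0) sdv else 1
    b <- coefficients[[nm]]
    eta <- eta + b[1L] * z + if (length(b) > 1L) b[2L] * z^2 else 0
  }
  s <- stats::plogis(eta)
  s[!stack$mask] <- NA_real_
  structure(list(surface = s, coefficients = coefficients,
                 intercept = intercept, stack = stack),
            class = "true_suitability")
}

#' Sample presence-only occurrences from a suitability surface
#'
#' Draws `n` distinct cells with probability proportional to suitability
#' (without replacement by default, matching the one-record-per-cell form
#' the model consumes) and records coordinates at cell centers.
#'
#' @param truth a [true_suitability].
#' @param n number of presence records.
#' @param seed integer seed.
#' @param species species id for the resulting set.
#' @param replace sample cells with replacement instead (then records are
#'   not deduplicated and `n` may exceed the support size).
#' @return an [occurrence_set].
#' @export
sample_occurrences <- function(truth, n, seed, species = "synthetic",
                               replace = FALSE) {
  s <- truth$surface
  w <- as.vector(t(s))             # row-major cell order
  w[is.na(w)] <- 0
  support <- sum(w > 0)
  if (!replace && n > support)
    stop(sprintf("n = %d exceeds the %d cells with positive suitability",
                 n, support))
  stack <- truth$stack
  with_seed(seed, {
    cells <- sample.int(length(w), n, replace = replace, prob = w)
    row <- (cells - 1L) %/% n_cols(stack) + 1L
    col <- (cells - 1L) %% n_cols(stack) + 1L
    ctr <- cell_center(stack, row, col)
    occurrence_set(species, ctr$x, ctr$y, stack, source = "synthetic",
                   dedup = !replace)
  })
}

#' Packaged four-species gradient study scenario
#'
#' A 150 x 150 landscape (90 m cells) with seven layers — temperature,
#' precipitation, elevation and a vegetation continuous field (gradient +
#' random field), a 6-class categorical cover layer, derived slope and
#' distance-to-water — and four species whose true response optima are
#' staggered along the temperature gradient so that adjacent niches
#' overlap strongly and the extreme pair weakly.  Sample sizes are 48, 38,
#' 34 and 14, the small presence-only regime the pipeline is designed for.
#'
#' @param seed integer seed; the whole fixture regenerates bit-identically
#'   from it.
#' @param n_rows,n_cols grid size (defaults 150 x 150).
#' @param n per-species sample sizes, largest first.
#' @return list with `stack` ([raster_stack]), `occurrences` (named list
#'   of four [occurrence_set]), `truth` (named list of four
#'   [true_suitability]), and the `scenario`.
#' @export
gradient_study_scenario <- function(seed = 1L, n_rows = 150L, n_cols = 150L,
                                    n = c(48L, 38L, 34L, 14L)) {
  optima <- c(-1.2, -0.4, 0.4, 1.2)    # temperature z-score optima
  quad <- -4                           # niche breadth (quadratic curvature)
  species <- list()
  for (i in seq_along(optima)) {
    ci <- optima[i]
    species[[paste0("species_", letters[i])]] <- list(
      n = n[i],
      intercept = 1.6 + quad * ci^2,
      coefficients = list(temperature  = c(-2 * quad * ci, quad),
                          precipitation = c(0.5, -0.4)))
  }
  scen <- synthetic_scenario(
    n_rows = n_rows, n_cols = n_cols, cellsize = 90,
    layers = list(
      list(name = "temperature",   base = 22,   gradient_x = -6,
           gradient_y = 0,    corr_length = 15, sd = 0.8),
      list(name = "precipitation", base = 1800, gradient_x = 0,
           gradient_y = -600, corr_length = 20, sd = 120),
      list(name = "elevation",     base = 600,  gradient_x = 100,
           gradient_y = 700,  corr_length = 12, sd = 120),
      list(name = "vegetation",    base = 60,   gradient_x = 0,
           gradient_y = 0,    corr_length = 10, sd = 12)),
    categorical = list(name = "landcover", n_classes = 6, corr_length = 8),
    slope_from = "elevation",
    distance_layers = list(list(name = "dist_water", n_sources = 40)),
    species = species, seed = seed)

  stack <- gen_landscape(scen)
  truth <- list(); occ <- list()
  for (i in seq_along(scen$species)) {
    nm <- names(scen$species)[i]
    sp <- scen$species[[i]]
    truth[[nm]] <- true_suitability(stack, sp$coefficients, sp$intercept)
    occ[[nm]] <- sample_occurrences(truth[[nm]], sp$n, seed = seed + i,
                                    species = nm)
  }
  list(stack = stack, occurrences = occ, truth = truth, scenario = scen)
}
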