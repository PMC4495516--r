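# Feature expansion for the maxent model.  Feature classes follow the
# classic maxent default rule by sample size: n < 10 linear only;
# 10 <= n < 15 linear + quadratic; n >= 15 linear + quadratic + hinge.
# Categorical layers always expand to one indicator per legend class.
# Every feature is min-max scaled to [0,1] using background extremes.

#' Select background cells
#'
#' All non-nodata cells when there are at most `cap`; otherwise a seeded
#' uniform subsample of `subsample` cells (the classic maxent default of
#' 10,000 background points).
#'
#' @param stack a [raster_stack].
#' @param cap maximum background size before subsampling.
#' @param subsample subsample size used above the cap.
#' @param seed seed for the subsample draw.
#' @return integer vector of row-major cell ids.
#' @export
background_cells <- function(stack, cap = 1e5, subsample = 1e4, seed = 1L) {
  valid <- which(t(stack$mask))          # row-major ids
  if (length(valid) > cap)
    valid <- sort(with_seed(seed, sample(valid, subsample)))
  valid
}

#' Build the maxent feature expansion over background cells
#'
#' @param stack a [raster_stack].
#' @param sample_size the species' presence sample size `n`, which selects
#'   feature classes by the default rule (see Details).
#' @param background integer row-major cell ids; default [background_cells].
#' @param hinge_knots number of hinge knots per continuous layer; forward
#'   and reverse hinges are built at each knot.
#' @param feature_classes override the sample-size rule with an explicit
#'   subset of `c("linear","quadratic","hinge")`.
#' @param seed seed for background subsampling.
#'
#' @details With `n < 10` only linear features are used; with
#' `10 <= n < 15` linear and quadratic; with `n >= 15` linear, quadratic
#' and hinge (50 knots per layer by default, forward and reverse).
#' Constant (zero-variance) layers are dropped with a warning.
#'
#' @return object of class `maxent_features`: `F` (cells x features matrix,
#'   values in [0,1]), `descriptors` (data.frame with `layer`, `class`,
#'   `param`), `cells` (row-major background cell ids), `classes`, and the
#'   originating `stack`.
#' @export
build_features <- function(stack, sample_size, background = NULL,
                           hinge_knots = 50L, feature_classes = NULL,
                           seed = 1L) {
  if (sample_size < 2) stop("sample_size must be >= 2")
  classes <- feature_classes %||% feature_classes_for_n(sample_size)
  if (is.null(background)) background <- background_cells(stack, seed = seed)
  nc <- n_cols(stack)
  row <- (background - 1L) %/% nc + 1L
  col <- (background - 1L) %% nc + 1L

  cols <- list(); desc <- list()
  add <- function(vals, layer, class, param) {
    rng <- range(vals)
    if (rng[2] - rng[1] <= 0) return(FALSE)
    cols[[length(cols) + 1L]] <<- (vals - rng[1]) / (rng[2] - rng[1])
    desc[[length(desc) + 1L]] <<- data.frame(layer = layer, class = class,
                                             param = param)
    TRUE
  }

  for (nm in names(stack$layers)) {
    v <- stack$layers[[nm]][cbind(row, col)]
    if (stack$kinds[[nm]] == "categorical") {
      for (code in stack$legends[[nm]])
        add(as.numeric(v == code), nm, "category", code)
      next
    }
    rng <- range(v)
    if (rng[2] - rng[1] <= 0) {
      warning(sprintf("layer '%s' is constant over the background; dropped", nm))
      next
    }
    if ("linear" %in% classes) add(v, nm, "linear", NA_real_)
    if ("quadratic" %in% classes) add(v^2, nm, "quadratic", NA_real_)
    if ("hinge" %in% classes && hinge_knots > 0L) {
      knots <- rng[1] + seq_len(hinge_knots) / (hinge_knots + 1) * (rng[2] - rng[1])
      for (t in knots) add(pmax(0, v - t) / (rng[2] - t), nm, "hinge", t)
      for (t in knots) add(pmax(0, t - v) / (t - rng[1]), nm, "hinge_rev", t)
    }
  }
  F <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, length(background), 0L)
  descriptors <- if (length(desc)) do.call(rbind, desc) else
    data.frame(layer = character(), class = character(), param = numeric())
  structure(list(F = F, descriptors = descriptors, cells = background,
                 classes = classes, hinge_knots = hinge_knots, stack = stack),
            class = "maxent_features")
}

feature_classes_for_n <- function(n) {
  if (n < 10) "linear"
  else if (n < 15) c("linear", "quadratic")
  else c("linear", "quadratic", "hinge")
}

#' @export
print.maxent_features <- function(x, ...) {
  cat(sprintf("maxent_features: %d background cells x %d features (%s)\n",
              nrow(x$F), ncol(x$F), paste(x$classes, collapse = "+")))
  invisible(x)
}

# default per-class regularization, piecewise linear in the presence sample
# size m (clamped at the table ends), following the classic maxent defaults
default_class_beta <- function(class, m) {
  tab <- switch(class,
    linear     = list(m = c(10, 30, 100), b = c(1.0, 0.2, 0.05)),
    quadratic  = list(m = c(10, 17, 30, 100), b = c(1.3, 0.8, 0.5, 0.05)),
    hinge      = ,
    hinge_rev  = list(m = c(10, 100), b = c(0.5, 0.5)),
    category   = list(m = c(10, 17), b = c(0.65, 0.25)),
    stop(sprintf("unknown feature class '%s'", class)))
  stats::approx(tab$m, tab$b, xout = m, rule = 2)$y
}

# map a vector over background cells back onto the grid (NA elsewhere)
vector_to_surface <- function(values, features) {
  stack <- features$stack
  m <- matrix(NA_real_, n_rows(stack), n_cols(stack))
  tm <- t(m)
  tm[features$cells] <- values
  t(tm)
}
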