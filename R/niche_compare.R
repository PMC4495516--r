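# Binary range maps and pairwise niche comparison: range overlap at a
# shared threshold, Schoener's D and the Hellinger-based I statistic on
# normalized suitability surfaces, and environmental summaries within
# predicted ranges.

#' Binarize a suitability surface
#'
#' A cell is predicted suitable iff its (logistic) suitability is at or
#' above the threshold; nodata cells are never predicted.  Area is
#' reported in km2 from the cell size.
#'
#' @param surface suitability matrix (NA = nodata).
#' @param threshold threshold in (0,1), e.g. from [mtp_threshold] or
#'   [shared_threshold].
#' @param cellsize cell size in meters.
#' @return object of class `binary_range`: logical `cells` matrix,
#'   `threshold`, `n_cells`, `area_km2`.
#' @export
binarize <- function(surface, threshold, cellsize) {
  cells <- !is.na(surface) & surface >= threshold
  structure(list(cells = cells, threshold = threshold,
                 n_cells = sum(cells),
                 area_km2 = sum(cells) * cellsize^2 / 1e6),
            class = "binary_range")
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf("binary_range: %d cells (%.2f km2) at threshold %.4g\n",
              x$n_cells, x$area_km2, x$threshold))
  invisible(x)
}

#' Species-averaged suitability threshold
#'
#' The arithmetic mean of per-species minimum-training-presence
#' thresholds, used as one shared threshold when comparing ranges across
#' species.
#'
#' @param thresholds non-empty numeric vector of per-species thresholds.
#' @return their mean.
#' @export
shared_threshold <- function(thresholds) {
  if (length(thresholds) == 0L) stop("no thresholds supplied")
  mean(thresholds)
}

#' Range overlap between two binary ranges
#'
#' `N_xy / min(N_x, N_y)`: the number of cells predicted for both species
#' over the smaller species' predicted-cell count; 1 when one range is a
#' subset of the other, 0 when disjoint.
#'
#' @param x,y [binarize] results on the same grid, both non-empty.
#' @return overlap in [0,1].
#' @export
range_overlap <- function(x, y) {
  if (!all(dim(x$cells) == dim(y$cells)))
    stop("ranges are on different grids")
  if (x$n_cells == 0L || y$n_cells == 0L)
    stop("range overlap is undefined for an empty predicted range")
  sum(x$cells & y$cells) / min(x$n_cells, y$n_cells)
}

# normalize two surfaces to probability distributions over their shared
# valid cells
normalize_pair <- function(sx, sy) {
  if (!all(dim(sx) == dim(sy))) stop("surfaces are on different grids")
  ok <- !is.na(sx) & !is.na(sy)
  p <- sx[ok]; q <- sy[ok]
  if (sum(p) <= 0 || sum(q) <= 0)
    stop("cannot normalize an all-zero suitability surface")
  list(p = p / sum(p), q = q / sum(q))
}

#' Schoener's D niche similarity
#'
#' Both suitability surfaces are normalized to sum 1 over the cells valid
#' in both, then `D = 1 - 0.5 * sum |p_i - q_i|`: 1 for identical
#' suitability distributions, 0 for disjoint ones.  Invariant to
#' multiplying either surface by a positive constant.
#'
#' @param sx,sy suitability matrices on the same grid.
#' @return D in [0,1].
#' @export
schoener_D <- function(sx, sy) {
  n <- normalize_pair(sx, sy)
  1 - 0.5 * sum(abs(n$p - n$q))
}

#' Hellinger-based I niche similarity
#'
#' With the same normalization as [schoener_D],
#' `I = 1 - 0.5 * sum (sqrt(p_i) - sqrt(q_i))^2` (one minus half the
#' squared Hellinger distance), on the same 0-1 scale; `I >= D` always.
#'
#' @param sx,sy suitability matrices on the same grid.
#' @return I in [0,1].
#' @export
similarity_I <- function(sx, sy) {
  n <- normalize_pair(sx, sy)
  1 - 0.5 * sum((sqrt(n$p) - sqrt(n$q))^2)
}

#' Pairwise similarity and overlap matrices
#'
#' @param surfaces named list of suitability matrices (one per species).
#' @return list with symmetric matrices `D` and `I` (diagonal 1).
#' @export
similarity_matrices <- function(surfaces) {
  k <- length(surfaces)
  D <- I <- matrix(1, k, k, dimnames = list(names(surfaces), names(surfaces)))
  if (k > 1) for (a in 1:(k - 1)) for (b in (a + 1):k) {
    D[a, b] <- D[b, a] <- schoener_D(surfaces[[a]], surfaces[[b]])
    I[a, b] <- I[b, a] <- similarity_I(surfaces[[a]], surfaces[[b]])
  }
  list(D = D, I = I)
}

#' @rdname similarity_matrices
#' @param ranges named list of [binarize] results.
#' @return `overlap_matrix`: symmetric range-overlap matrix (diagonal 1).
#' @export
overlap_matrix <- function(ranges) {
  k <- length(ranges)
  M <- matrix(1, k, k, dimnames = list(names(ranges), names(ranges)))
  if (k > 1) for (a in 1:(k - 1)) for (b in (a + 1):k)
    M[a, b] <- M[b, a] <- range_overlap(ranges[[a]], ranges[[b]])
  M
}

#' Environmental conditions within a predicted range
#'
#' Mean and standard deviation of continuous layer values over the
#' predicted (non-nodata) cells.
#'
#' @param stack a [raster_stack].
#' @param range a [binarize] result on the stack's grid.
#' @param layers names of continuous layers to summarize; defaults to all.
#' @return data.frame with `layer`, `mean`, `sd`, `n_cells`.
#' @export
env_summary <- function(stack, range, layers = NULL) {
  if (is.null(layers))
    layers <- names(stack$layers)[stack$kinds == "continuous"]
  if (any(stack$kinds[layers] != "continuous"))
    stop("env_summary needs continuous layers")
  sel <- range$cells & stack$mask
  if (!any(sel)) stop("predicted range is empty")
  do.call(rbind, lapply(layers, function(nm) {
    v <- stack$layers[[nm]][sel]
    data.frame(layer = nm, mean = mean(v), sd = stats::sd(v),
               n_cells = length(v))
  }))
}

#' Shared occurrence localities between species
#'
#' Pairwise counts of grid cells that appear in both species' occurrence
#' sets (records snapped to a common grid); the diagonal holds each
#' species' own cell count.
#'
#' @param sets named list of [occurrence_set] on the same grid.
#' @return symmetric integer matrix of shared-cell counts.
#' @export
shared_occurrence_localities <- function(sets) {
  keys <- lapply(sets, function(s) paste(s$row, s$col))
  k <- length(sets)
  M <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (a in seq_len(k)) for (b in seq_len(k))
    M[a, b] <- length(intersect(keys[[a]], keys[[b]]))
  M
}
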