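#' Derive a slope layer from elevation
#'
#' Computes slope in degrees from the local elevation gradient using Horn's
#' 3x3 weighted finite-difference method, the standard used by GIS terrain
#' tools.  Grid-border cells and neighbours that are nodata are filled by
#' edge replication before differencing; cells whose own elevation is
#' nodata stay nodata.
#'
#' @param stack a [raster_stack].
#' @param elevation_layer name of the continuous elevation layer (m).
#' @param name name for the new slope layer.
#' @return the stack with a `slope` layer (degrees, `0 <= slope < 90`)
#'   appended.
#' @export
slope_from_elevation <- function(stack, elevation_layer = "elevation",
                                 name = "slope") {
  if (!elevation_layer %in% names(stack$layers))
    stop(sprintf("no layer '%s'", elevation_layer))
  if (stack$kinds[[elevation_layer]] != "continuous")
    stop(sprintf("layer '%s' is categorical; slope needs a continuous elevation layer",
                 elevation_layer))
  z <- stack$layers[[elevation_layer]]
  nr <- nrow(z); nc <- ncol(z); cs <- stack$cellsize

  # pad by edge replication, then fill remaining NAs with the cell's own value
  zp <- z[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  shift <- function(dr, dc) zp[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc]
  nb <- list(a = shift(-1L, -1L), b = shift(-1L, 0L), c = shift(-1L, 1L),
             d = shift(0L, -1L),                      f = shift(0L, 1L),
             g = shift(1L, -1L),  h = shift(1L, 0L),  i = shift(1L, 1L))
  nb <- lapply(nb, function(m) ifelse(is.na(m), z, m))

  dzdx <- ((nb$c + 2 * nb$f + nb$i) - (nb$a + 2 * nb$d + nb$g)) / (8 * cs)
  dzdy <- ((nb$g + 2 * nb$h + nb$i) - (nb$a + 2 * nb$b + nb$c)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  slope[is.na(z)] <- NA_real_
  add_layer(stack, name, slope, kind = "continuous")
}

#' Euclidean distance-to-source layer
#'
#' For each cell, the straight-line distance in meters from its center to
#' the nearest source cell's center (0 at source cells).  This mirrors the
#' GIS practice of rasterizing vector features (rivers, villages) before
#' taking Euclidean distances, so distances are discretized to cell
#' centers rather than true vector geometry.
#'
#' @param stack a [raster_stack].
#' @param sources either a two-column matrix/data.frame of projected
#'   `(x, y)` coordinates, or a logical matrix on the stack's grid marking
#'   source cells.
#' @param name name for the new distance layer.
#' @return the stack with the distance layer appended (meters).
#' @export
euclidean_distance_layer <- function(stack, sources, name = "distance") {
  nr <- n_rows(stack); nc <- n_cols(stack); cs <- stack$cellsize
  if (is.logical(sources) && is.matrix(sources)) {
    if (!all(dim(sources) == dim(stack$mask)))
      stop("source mask must match the grid dimensions")
    idx <- which(sources, arr.ind = TRUE)
    src_row <- idx[, 1L]; src_col <- idx[, 2L]
  } else {
    sources <- as.matrix(sources)
    snapped <- snap_to_cell(stack, sources[, 1L], sources[, 2L])
    keep <- !is.na(snapped$row)
    src_row <- snapped$row[keep]; src_col <- snapped$col[keep]
  }
  if (length(src_row) == 0L)
    stop("no source locations fall inside the grid")

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- matrix(Inf, nr, nc)
  for (k in seq_along(src_row)) {
    dk <- (rows - src_row[k])^2 + (cols - src_col[k])^2
    d2 <- pmin(d2, dk)
  }
  dist <- sqrt(d2) * cs
  dist[!stack$mask] <- NA_real_
  add_layer(stack, name, dist, kind = "continuous")
}
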