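#' Presence records for one species, snapped to a grid
#'
#' Constructs an `occurrence_set`: presence-only records in projected
#' coordinates, snapped to the cells of a [raster_stack].  Records falling
#' on nodata cells are dropped with a warning, and (by default) multiple
#' records in the same cell are collapsed to one, the usual presence-only
#' convention that keeps one presence per modelling unit.
#'
#' @param species species identifier (single string).
#' @param x,y record coordinates, projected meters.
#' @param stack the [raster_stack] defining the grid.
#' @param source optional per-record source tag (e.g. `"camera-trap"`,
#'   `"sighting"`).
#' @param dedup collapse within-cell duplicates to one record?
#' @return An object of class `occurrence_set`: list with `species`, `x`,
#'   `y`, `source`, `row`, `col` (post-snap cell indices).
#' @export
occurrence_set <- function(species, x, y, stack, source = NULL,
                           dedup = TRUE) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (is.null(source)) source <- rep("unknown", length(x))
  snapped <- snap_to_cell(stack, x, y)
  on_grid <- !is.na(snapped$row)
  valid <- on_grid
  valid[on_grid] <- stack$mask[cbind(snapped$row[on_grid], snapped$col[on_grid])]
  if (any(!valid))
    warning(sprintf("%s: dropped %d record(s) on nodata or off-grid cells",
                    species, sum(!valid)))
  x <- x[valid]; y <- y[valid]; source <- source[valid]
  row <- snapped$row[valid]; col <- snapped$col[valid]
  if (dedup) {
    keep <- !duplicated(cbind(row, col))
    x <- x[keep]; y <- y[keep]; source <- source[keep]
    row <- row[keep]; col <- col[keep]
  }
  if (length(x) == 0L)
    stop(sprintf("species '%s' has no usable records", species))
  structure(list(species = species, x = x, y = y, source = source,
                 row = row, col = col),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: '%s', %d record(s) on distinct grid cells\n",
              x$species, length(x$x)))
  invisible(x)
}

#' @export
length.occurrence_set <- function(x) length(x$x)

#' Read species occurrences from CSV
#'
#' Expects a UTF-8 CSV with header columns `species,x,y` and optionally
#' `source`; coordinates must be in the stack's projected system.  Records
#' are snapped to cells, nodata records dropped with a warning, and
#' within-cell duplicates merged per species (see [occurrence_set]).
#'
#' @param path CSV file path.
#' @param stack the [raster_stack] defining the grid.
#' @param dedup collapse within-cell duplicates?
#' @return named list of [occurrence_set], one per species, in order of
#'   first appearance.
#' @export
read_occurrences <- function(path, stack, dedup = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y")
  if (!all(need %in% names(df)))
    stop(sprintf("occurrence CSV must have columns %s (found: %s)",
                 paste(need, collapse = ","), paste(names(df), collapse = ",")))
  src <- if ("source" %in% names(df)) df$source else rep("unknown", nrow(df))
  out <- list()
  for (sp in unique(df$species)) {
    i <- df$species == sp
    out[[sp]] <- occurrence_set(sp, df$x[i], df$y[i], stack,
                                source = src[i], dedup = dedup)
  }
  out
}

#' Write occurrence sets to CSV
#' @param sets a list of [occurrence_set] (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(sets, path) {
  if (inherits(sets, "occurrence_set")) sets <- list(sets)
  df <- do.call(rbind, lapply(sets, function(s)
    data.frame(species = s$species, x = s$x, y = s$y, source = s$source)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# row-major linear cell ids for occurrence cells (used to match background)
occ_cell_ids <- function(occ, stack) {
  (occ$row - 1L) * n_cols(stack) + occ$col
}
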