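#' Aligned multi-layer environmental grid
#'
#' A `raster_stack` holds one or more environmental layers on a single
#' aligned grid: continuous layers (real values in natural units) and
#' categorical layers (integer class codes with a legend).  All layers share
#' the same geometry and a common nodata mask; a cell that is nodata in any
#' layer is treated as nodata everywhere, because downstream modelling needs
#' a complete feature vector for every background cell.
#'
#' Grid convention: projected coordinates in meters, cell-center
#' registration, row 1 at the top (map north).  `xll`/`yll` are the
#' coordinates of the lower-left *corner* of the grid, as in the ESRI ASCII
#' grid format.
#'
#' @param layers named list of numeric matrices (`n_rows x n_cols`), `NA`
#'   for nodata.  Row 1 is the northernmost row.
#' @param kinds character vector, one of `"continuous"` or `"categorical"`
#'   per layer.  Recycled if length 1.
#' @param xll,yll coordinates (m) of the lower-left corner.
#' @param cellsize cell size in meters (> 0).
#' @param crs free-form coordinate-system tag (opaque string).
#' @param legends named list: for each categorical layer, an integer vector
#'   of admissible class codes.  Defaults to the codes observed.
#'
#' @return An object of class `raster_stack` with elements `layers`,
#'   `kinds`, `legends`, `xll`, `yll`, `cellsize`, `crs`, `mask` (logical
#'   matrix, `TRUE` = valid data).
#' @export
raster_stack <- function(layers, kinds = "continuous", xll = 0, yll = 0,
                         cellsize = 1, crs = "unknown", legends = list()) {
  if (!is.list(layers) || length(layers) < 1L)
    stop("`layers` must be a non-empty named list of matrices")
  if (is.null(names(layers)) || anyDuplicated(names(layers)) ||
      any(!nzchar(names(layers))))
    stop("`layers` must have unique non-empty names")
  if (!all(vapply(layers, is.matrix, logical(1))))
    stop("every layer must be a matrix")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share the same dimensions")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  kinds <- rep_len(kinds, length(layers))
  if (!all(kinds %in% c("continuous", "categorical")))
    stop("layer kinds must be 'continuous' or 'categorical'")
  names(kinds) <- names(layers)

  # shared nodata mask: union of per-layer nodata
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  layers <- lapply(layers, function(m) {
    m[!mask] <- NA_real_
    storage.mode(m) <- "double"
    m
  })

  for (nm in names(layers)[kinds == "categorical"]) {
    v <- layers[[nm]][mask]
    if (any(v != round(v)))
      stop(sprintf("categorical layer '%s' has non-integer codes", nm))
    if (is.null(legends[[nm]])) {
      legends[[nm]] <- sort(unique(as.integer(v)))
    } else if (!all(v %in% legends[[nm]])) {
      stop(sprintf("categorical layer '%s' contains codes not in its legend", nm))
    }
  }

  structure(
    list(layers = layers, kinds = kinds, legends = legends,
         xll = xll, yll = yll, cellsize = cellsize, crs = crs, mask = mask),
    class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("raster_stack: %d layer(s), %d x %d cells, cellsize %g m\n",
              length(x$layers), d[1], d[2], x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]  (%s)\n",
              x$xll, x$xll + d[2] * x$cellsize,
              x$yll, x$yll + d[1] * x$cellsize, x$crs))
  cat(sprintf("  valid cells: %d / %d\n", sum(x$mask), length(x$mask)))
  kinds <- ifelse(x$kinds == "categorical", " [cat]", "")
  cat("  layers:", paste0(names(x$layers), kinds, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.raster_stack <- function(x) dim(x$mask)

n_rows <- function(stack) nrow(stack$mask)
n_cols <- function(stack) ncol(stack$mask)

#' Cell-center coordinates
#'
#' @param stack a `raster_stack`.
#' @param row,col cell indices (row 1 = top).
#' @return list with numeric `x` and `y` cell-center coordinates (m).
#' @export
cell_center <- function(stack, row, col) {
  ytop <- stack$yll + n_rows(stack) * stack$cellsize
  list(x = stack$xll + (col - 0.5) * stack$cellsize,
       y = ytop - (row - 0.5) * stack$cellsize)
}

#' Snap point coordinates to cell indices
#'
#' Cell membership is half-open: `[x0, x0 + cs)` horizontally and
#' `(ytop - cs, ytop]` vertically, so a point on a shared edge belongs to
#' the cell to its right / below it.  Points outside the grid get `NA`.
#'
#' @param stack a `raster_stack`.
#' @param x,y point coordinates in the grid's projected system (m).
#' @return list with integer vectors `row` and `col` (`NA` = off-grid).
#' @export
snap_to_cell <- function(stack, x, y) {
  cs <- stack$cellsize
  ytop <- stack$yll + n_rows(stack) * cs
  col <- floor((x - stack$xll) / cs) + 1L
  row <- floor((ytop - y) / cs) + 1L
  bad <- col < 1L | col > n_cols(stack) | row < 1L | row > n_rows(stack)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$mask) == dim(b$mask)) &&
    abs(a$xll - b$xll) <= tol && abs(a$yll - b$yll) <= tol &&
    abs(a$cellsize - b$cellsize) <= tol
}

# ---- ESRI ASCII grid I/O ---------------------------------------------------

read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read raster file '%s'", path))
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  n_hdr <- 0L
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      n_hdr <- n_hdr + 1L
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("'%s' is not an ESRI ASCII grid (missing header keys)", path))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("'%s': expected %d values, found %d", path, nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

write_ascii_grid <- function(m, path, xll, yll, cellsize, nodata = -9999) {
  out <- m
  out[is.na(out)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.17g", xll),
               sprintf("yllcorner %.17g", yll),
               sprintf("cellsize %.17g", cellsize),
               sprintf("NODATA_value %g", nodata)), con)
  writeLines(apply(out, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  invisible(path)
}

#' Read an aligned stack of single-band grids
#'
#' Reads ESRI ASCII grids and assembles them into a [raster_stack],
#' verifying that every layer shares the grid geometry of the first and
#' taking the union of the per-layer nodata masks.  Alternatively pass a
#' single YAML sidecar file (as written by [write_raster_stack]) listing
#' the layers, kinds and legends.
#'
#' @param paths character vector of `.asc` file paths, or a single `.yml`
#'   sidecar path.
#' @param kinds `"continuous"`/`"categorical"` per layer (ignored when
#'   reading a sidecar, which records kinds itself).
#' @param names layer names; defaults to file base names.
#' @param crs coordinate-system tag.
#' @return a [raster_stack].
#' @export
read_raster_stack <- function(paths, kinds = "continuous", names = NULL,
                              crs = "unknown") {
  if (length(paths) == 1L && grepl("\\.ya?ml$", paths)) {
    side <- yaml::read_yaml(paths)
    dir <- dirname(paths)
    paths2 <- vapply(side$layers, function(l) file.path(dir, l$file), character(1))
    kinds <- vapply(side$layers, function(l) l$kind, character(1))
    names <- vapply(side$layers, function(l) l$name, character(1))
    legends <- list()
    for (l in side$layers)
      if (!is.null(l$legend)) legends[[l$name]] <- as.integer(unlist(l$legend))
    crs <- if (!is.null(side$crs)) side$crs else "unknown"
    return(build_stack_from_files(paths2, kinds, names, crs, legends))
  }
  if (is.null(names)) names <- sub("\\.[^.]*$", "", basename(paths))
  build_stack_from_files(paths, rep_len(kinds, length(paths)), names, crs,
                         list())
}

build_stack_from_files <- function(paths, kinds, names, crs, legends) {
  grids <- lapply(paths, read_ascii_grid)
  g1 <- grids[[1L]]
  for (i in seq_along(grids)[-1L]) {
    g <- grids[[i]]
    if (!all(dim(g$values) == dim(g1$values)) ||
        abs(g$xll - g1$xll) > 1e-9 || abs(g$yll - g1$yll) > 1e-9 ||
        abs(g$cellsize - g1$cellsize) > 1e-9)
      stop(sprintf("layer '%s' (%s) does not align with layer '%s'",
                   names[i], paths[i], names[1L]))
  }
  layers <- stats::setNames(lapply(grids, `[[`, "values"), names)
  raster_stack(layers, kinds = kinds, xll = g1$xll, yll = g1$yll,
               cellsize = g1$cellsize, crs = crs, legends = legends)
}

#' Write a raster stack as ESRI ASCII grids plus a YAML sidecar
#'
#' One `.asc` file per layer and a `stack.yml` sidecar recording layer
#' order, kinds, legends and the coordinate-system tag, so that
#' [read_raster_stack] on the sidecar reproduces the stack exactly.
#'
#' @param stack a [raster_stack].
#' @param dir output directory (created if missing).
#' @return path of the sidecar file, invisibly.
#' @export
write_raster_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (nm in names(stack$layers)) {
    f <- paste0(nm, ".asc")
    write_ascii_grid(stack$layers[[nm]], file.path(dir, f),
                     stack$xll, stack$yll, stack$cellsize)
    e <- list(name = nm, file = f, kind = unname(stack$kinds[[nm]]))
    if (!is.null(stack$legends[[nm]])) e$legend <- as.integer(stack$legends[[nm]])
    entries[[length(entries) + 1L]] <- e
  }
  side <- file.path(dir, "stack.yml")
  yaml::write_yaml(list(crs = stack$crs, layers = entries), side)
  invisible(side)
}

#' Add or replace a layer
#' @param stack a [raster_stack].
#' @param name layer name.
#' @param values numeric matrix on the stack's grid.
#' @param kind `"continuous"` or `"categorical"`.
#' @return the updated stack (mask re-unioned).
#' @export
add_layer <- function(stack, name, values, kind = "continuous") {
  layers <- stack$layers
  layers[[name]] <- values
  kinds <- stack$kinds
  kinds[[name]] <- kind
  raster_stack(layers, kinds = kinds[names(layers)], xll = stack$xll,
               yll = stack$yll, cellsize = stack$cellsize, crs = stack$crs,
               legends = stack$legends)
}

#' Extract layer values at cells
#' @param stack a [raster_stack].
#' @param layer layer name.
#' @param row,col cell indices.
#' @return numeric vector of layer values.
#' @export
layer_values <- function(stack, layer, row, col) {
  if (!layer %in% names(stack$layers)) stop(sprintf("no layer '%s'", layer))
  stack$layers[[layer]][cbind(row, col)]
}
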