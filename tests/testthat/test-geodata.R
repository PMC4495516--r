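test_that("stack construction enforces alignment and unions nodata masks", {
  a <- matrix(1, 10, 10); a[1, 1] <- NA
  b <- matrix(2, 10, 10); b[10, 10] <- NA
  stk <- raster_stack(list(a = a, b = b), cellsize = 90)
  expect_s3_class(stk, "raster_stack")
  expect_length(stk$layers, 2)
  expect_false(stk$mask[1, 1])
  expect_false(stk$mask[10, 10])
  expect_equal(sum(stk$mask), 98)
  # the union mask is applied to every layer
  expect_true(is.na(stk$layers$a[10, 10]))
  expect_true(is.na(stk$layers$b[1, 1]))

  expect_error(raster_stack(list(a = a, b = matrix(1, 5, 5))), "dimensions")
  expect_error(raster_stack(list(a = a), cellsize = 0), "positive")
  expect_error(raster_stack(list(a = matrix(1.5, 2, 2)),
                            kinds = "categorical"), "non-integer")
  expect_error(raster_stack(list(a = matrix(3, 2, 2)), kinds = "categorical",
                            legends = list(a = 1:2)), "legend")
})

test_that("ascii-grid round trips preserve values, geometry and mask exactly", {
  set.seed(7)
  layers <- stats::setNames(
    lapply(1:25, function(i) {
      m <- matrix(rnorm(20 * 15), 20, 15)
      if (i == 3) m[2, 2] <- NA
      m
    }), paste0("env", 1:25))
  layers$cover <- matrix(sample(1:4, 300, TRUE), 20, 15)
  stk <- raster_stack(layers, kinds = c(rep("continuous", 25), "categorical"),
                      xll = 1000.25, yll = -50.5, cellsize = 90,
                      crs = "UTM48N")
  dir <- withr::local_tempdir()
  side <- write_raster_stack(stk, dir)
  back <- read_raster_stack(side)
  expect_identical(back$layers, stk$layers)      # bit-identical values
  expect_identical(back$mask, stk$mask)
  expect_equal(back$xll, stk$xll)
  expect_equal(back$yll, stk$yll)
  expect_equal(back$cellsize, stk$cellsize)
  expect_identical(back$kinds, stk$kinds)
  expect_identical(back$legends$cover, stk$legends$cover)
  expect_identical(back$crs, "UTM48N")
})

test_that("misaligned layers are rejected with the offending layer named", {
  dir <- withr::local_tempdir()
  nichemax:::write_ascii_grid(matrix(1, 5, 5), file.path(dir, "a.asc"), 0, 0, 90)
  nichemax:::write_ascii_grid(matrix(1, 5, 5), file.path(dir, "b.asc"), 0, 0, 30)
  expect_error(read_raster_stack(file.path(dir, c("a.asc", "b.asc"))),
               "'b'.*does not align")
  expect_error(read_raster_stack(file.path(dir, "missing.asc")), "cannot read")
})

test_that("point snapping follows the half-open cell-membership convention", {
  stk <- raster_stack(list(v = matrix(0, 4, 4)), xll = 0, yll = 0, cellsize = 10)
  # interior point
  s <- snap_to_cell(stk, 5, 35)
  expect_equal(c(s$row, s$col), c(1L, 1L))
  # point on a vertical shared edge belongs to the cell to its right
  s <- snap_to_cell(stk, 10, 35)
  expect_equal(c(s$row, s$col), c(1L, 2L))
  # point on a horizontal shared edge belongs to the cell below it
  s <- snap_to_cell(stk, 5, 30)
  expect_equal(c(s$row, s$col), c(2L, 1L))
  # top edge of the grid still belongs to row 1
  s <- snap_to_cell(stk, 5, 40)
  expect_equal(c(s$row, s$col), c(1L, 1L))
  # off-grid
  expect_true(is.na(snap_to_cell(stk, -1, 5)$row))
})

test_that("slope is zero on a constant plane and 45 degrees on a unit ramp", {
  flat <- fun_stack(8, 8, f = function(x, y) 500, name = "elevation")
  s <- slope_from_elevation(flat)
  expect_true(all(s$layers$slope == 0))

  ramp <- fun_stack(8, 8, f = function(x, y) x, name = "elevation")
  s <- slope_from_elevation(ramp)
  expect_equal(s$layers$slope[2:7, 2:7], matrix(45, 6, 6), tolerance = 1e-12)

  expect_error(slope_from_elevation(
    raster_stack(list(elevation = matrix(1L, 3, 3)), kinds = "categorical")),
    "categorical")
  expect_error(slope_from_elevation(flat, "nope"), "no layer")
})

test_that("slope matches an independent central-difference oracle on smooth surfaces", {
  # for z = g(x) + h(y), Horn's weighted differences reduce exactly to the
  # central differences of g and h, giving an analytic oracle
  set.seed(11)
  a <- runif(3, -2, 2); b <- runif(3, -2, 2)
  g <- function(x) a[1] * x + a[2] * sin(x / 3) + a[3] * (x / 10)^2
  h <- function(y) b[1] * y + b[2] * cos(y / 4) + b[3] * (y / 12)^2
  stk <- fun_stack(12, 14, cellsize = 2,
                   f = function(x, y) g(x) + h(y), name = "elevation")
  s <- slope_from_elevation(stk)$layers$slope
  z <- stk$layers$elevation
  cs <- 2
  for (r in 2:11) for (c in 2:13) {
    dzdx <- (z[r, c + 1] - z[r, c - 1]) / (2 * cs)
    dzdy <- (z[r + 1, c] - z[r - 1, c]) / (2 * cs)  # y decreases with row
    expect_equal(s[r, c], atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi,
                 tolerance = 1e-9)
  }
  expect_true(all(s >= 0 & s < 90))
})

test_that("distance layer matches its definition and a brute-force scan", {
  stk <- raster_stack(list(v = matrix(0, 11, 11)), cellsize = 90)
  ctr <- cell_center(stk, 6, 6)
  d <- euclidean_distance_layer(stk, cbind(ctr$x, ctr$y))$layers$distance
  for (r in c(1, 4, 11)) for (c in c(2, 6, 9))
    expect_equal(d[r, c], sqrt((r - 6)^2 + (c - 6)^2) * 90, tolerance = 1e-9)
  expect_equal(d[6, 6], 0)

  # all cells sources -> zero layer
  all_src <- matrix(TRUE, 11, 11)
  expect_true(all(euclidean_distance_layer(stk, all_src)$layers$distance == 0))

  # 20 random sources on a 50x50 grid vs exhaustive nearest-source scan
  set.seed(3)
  big <- raster_stack(list(v = matrix(0, 50, 50)), cellsize = 30)
  src <- matrix(FALSE, 50, 50)
  src[sample.int(2500, 20)] <- TRUE
  d <- euclidean_distance_layer(big, src)$layers$distance
  si <- which(src, arr.ind = TRUE)
  for (r in seq(1, 50, by = 7)) for (c in seq(1, 50, by = 7)) {
    best <- min(sqrt((si[, 1] - r)^2 + (si[, 2] - c)^2)) * 30
    expect_equal(d[r, c], best, tolerance = 1e-9)
  }
  # zero exactly on sources, strictly positive elsewhere
  expect_true(all(d[src] == 0))
  expect_true(all(d[!src] > 0))
  expect_error(euclidean_distance_layer(stk, matrix(FALSE, 11, 11)),
               "no source")
})

test_that("occurrence reading snaps, deduplicates and drops nodata records", {
  stk <- raster_stack(list(v = matrix(0, 5, 5)), cellsize = 10)
  # three points in three distinct cells
  o <- occurrence_set("sp", c(5, 15, 25), c(45, 45, 45), stk)
  expect_length(o, 3)
  # two points in the same cell collapse to one
  o <- occurrence_set("sp", c(5, 7), c(45, 43), stk)
  expect_length(o, 1)
  # deduplication is idempotent
  o2 <- occurrence_set(o$species, o$x, o$y, stk)
  expect_equal(length(o2), length(o))

  # CSV fixture: 15 records, one on a nodata cell
  m <- matrix(0, 5, 5); m[3, 3] <- NA
  stk2 <- raster_stack(list(v = m), cellsize = 10)
  pts <- expand.grid(col = 1:5, row = 1:3)[1:15, ]
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(species = "sp",
                       x = pts$col * 10 - 5, y = 50 - pts$row * 10 + 5),
            csv, row.names = FALSE)
  expect_warning(sets <- read_occurrences(csv, stk2), "dropped 1 record")
  expect_length(sets$sp, 14)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sp = "a", lon = 1, lat = 2), bad, row.names = FALSE)
  expect_error(read_occurrences(bad, stk), "columns")

  # species with zero usable records
  csv2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(species = "ghost", x = 25, y = 25), csv2,
            row.names = FALSE)
  expect_error(suppressWarnings(read_occurrences(csv2, stk2)),
               "no usable records")
})

test_that("occurrences round-trip through the CSV writer", {
  stk <- raster_stack(list(v = matrix(0, 6, 6)), cellsize = 10)
  o1 <- occ_at_cells(stk, c(1, 3, 5), c(2, 4, 6), species = "a")
  o2 <- occ_at_cells(stk, c(2, 2), c(1, 5), species = "b")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(list(o1, o2), csv)
  back <- read_occurrences(csv, stk)
  expect_named(back, c("a", "b"))
  expect_equal(back$a$row, o1$row)
  expect_equal(back$a$col, o1$col)
})
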