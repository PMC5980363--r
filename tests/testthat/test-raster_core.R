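test_that("ASCII grid write/read round trip preserves values, transform, nodata", {
  set.seed(11)
  g <- fixture_grid(matrix(rnorm(12), 3, 4))
  g$values[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(g, path)
  g2 <- read_asc(path)
  expect_identical(g2$values, g$values)
  expect_true(same_grid(g, g2))
  # nodata cell stays excluded from statistics
  expect_equal(mean(g2$values, na.rm = TRUE), mean(g$values, na.rm = TRUE))
})

test_that("read_asc fails loudly on missing files and bad headers", {
  expect_error(read_asc("/nonexistent/file.asc"), "no such file")
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "1 2"), path)
  expect_error(read_asc(path), "missing")
})

test_that("alignment is a no-op on the template grid and idempotent", {
  land <- fixture_landscape(40, seed = 3)$land
  dem <- land$dem
  out <- resample_to(dem, dem)
  expect_identical(out$values, dem$values)
  st <- align_stack(list(dem, land$climate$bio1), dem)
  st2 <- align_stack(unclass(st), dem)
  expect_identical(st2$bio1$values, st$bio1$values)
  expect_identical(st2$dem$values, st$dem$values)
})

test_that("bilinear resampling preserves constants and reproduces a linear ramp", {
  # 2x-finer constant layer
  fine <- raster_grid(matrix(7, 20, 20), xmin = 0, ymax = 2, cellsize = 0.1)
  coarse_tmpl <- raster_grid(matrix(0, 10, 10), xmin = 0, ymax = 2,
                             cellsize = 0.2)
  out <- resample_to(fine, coarse_tmpl)
  inner <- out$values[2:9, 2:9]
  expect_true(all(inner == 7))
  # analytic ramp z = 3 + 2*lon - 5*lat evaluated at output cell centers
  lon_f <- 0 + (seq_len(20) - 0.5) * 0.1
  lat_f <- 2 - (seq_len(20) - 0.5) * 0.1
  ramp <- outer(lat_f, lon_f, function(la, lo) 3 + 2 * lo - 5 * la)
  rg <- raster_grid(ramp, xmin = 0, ymax = 2, cellsize = 0.1)
  out <- resample_to(rg, coarse_tmpl)
  lon_c <- 0 + (seq_len(10) - 0.5) * 0.2
  lat_c <- 2 - (seq_len(10) - 0.5) * 0.2
  expected <- outer(lat_c, lon_c, function(la, lo) 3 + 2 * lo - 5 * la)
  expect_equal(out$values[2:9, 2:9], expected[2:9, 2:9], tolerance = 1e-12)
})

test_that("categorical resampling uses nearest neighbor and unknown methods fail", {
  fine <- raster_grid(matrix(rep(c(1, 2), each = 10), 10, 2), xmin = 0,
                      ymax = 1, cellsize = 0.1)
  expect_error(align_stack(list(fine), fine, methods = "cubic"),
               "unknown resampling method")
})

test_that("disjoint extents are rejected", {
  a <- raster_grid(matrix(1, 5, 5), xmin = 0, ymax = 1, cellsize = 0.1)
  b <- raster_grid(matrix(1, 5, 5), xmin = 50, ymax = 1, cellsize = 0.1)
  expect_error(resample_to(b, a), "disjoint")
})

test_that("pixel areas follow the cosine-of-latitude formula", {
  # 30 arc-sec cell centered on the equator
  g <- raster_grid(matrix(0, 2, 1), xmin = 0, ymax = 1 / 120, cellsize = 1 / 120)
  # row centers at +-1/480 deg; compare to the formula at those latitudes
  a1 <- pixel_area_km2(g, 1)
  expect_equal(a1, (0.5 / 60 * 111.195)^2 * cos((1 / 240) * pi / 180),
               tolerance = 1e-12)
  expect_equal(a1, 0.8588, tolerance = 2e-4)
  # symmetric rows about the equator have equal areas
  expect_equal(pixel_area_km2(g, 1), pixel_area_km2(g, 2))
  # cell centered at 60 N is exactly half the equatorial-center area
  g60 <- raster_grid(matrix(0, 1, 1), xmin = 0, ymax = 60 + 1 / 240,
                     cellsize = 1 / 120)
  g0 <- raster_grid(matrix(0, 1, 1), xmin = 0, ymax = 1 / 240,
                    cellsize = 1 / 120)
  expect_equal(pixel_area_km2(g60, 1) / pixel_area_km2(g0, 1), 0.5,
               tolerance = 1e-12)
  expect_error(
    pixel_area_km2(raster_grid(matrix(0, 1, 1), 0, 90.5, 1), 1), "latitude")
})

test_that("summed pixel areas reproduce the area of a 1x1 degree equatorial box", {
  g <- raster_grid(matrix(1, 120, 120), xmin = 0, ymax = 0.5,
                   cellsize = 1 / 120)
  total <- sum(pixel_area_km2(g, seq_len(120)) * 120)
  expect_lt(abs(total - 111.195^2) / 111.195^2, 0.005)
  expect_equal(binary_area_km2(g), total)
})

test_that("point-in-cell uses half-open intervals, north-up", {
  g <- raster_grid(matrix(1:9, 3, 3), xmin = 0, ymax = 3, cellsize = 1)
  # cell interior
  expect_equal(unlist(cell_index(g, 0.5, 2.5)), c(row = 1, col = 1))
  # west edge belongs to the cell, east edge to the next
  expect_equal(cell_index(g, 1, 2.5)$col, 2L)
  # north edge of the grid belongs to row 1; internal lat boundary to the cell below
  expect_equal(cell_index(g, 0.5, 3)$row, 1L)
  expect_equal(cell_index(g, 0.5, 2)$row, 2L)
  # outside
  expect_true(is.na(cell_index(g, -0.1, 1)$row))
})
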