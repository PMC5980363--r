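mk_map <- function(v, nr = 6, nc = 6, ymax = 38) {
  raster_grid(matrix(v, nr, nc), xmin = 72, ymax = ymax, cellsize = 1 / 120)
}

test_that("change categories are determined by the (present, future) bit pair", {
  p <- mk_map(c(1, 0, 1, 0), 2, 2)
  f <- mk_map(c(1, 1, 0, 0), 2, 2)
  ch <- classify_change(p, f)
  expect_equal(as.vector(ch$values), c(1, 2, 3, 0))  # stable, gain, loss, non
  p$values[1, 2] <- NA
  expect_true(is.na(classify_change(p, f)$values[1, 2]))
  expect_error(classify_change(p, mk_map(1, 3, 3)), "do not match")
})

test_that("category counts match brute-force enumeration on random maps", {
  set.seed(6)
  for (trial in 1:10) {
    p <- mk_map(rbinom(36, 1, 0.5))
    f <- mk_map(rbinom(36, 1, 0.5))
    ch <- classify_change(p, f)
    expect_equal(sum(ch$values == 1), sum(p$values == 1 & f$values == 1))
    expect_equal(sum(ch$values == 2), sum(p$values == 0 & f$values == 1))
    expect_equal(sum(ch$values == 3), sum(p$values == 1 & f$values == 0))
    expect_equal(sum(ch$values == 0), sum(p$values == 0 & f$values == 0))
  }
})

test_that("area accounting conserves the present suitable area and partitions the grid", {
  set.seed(8)
  p <- mk_map(rbinom(36, 1, 0.4))
  f <- mk_map(rbinom(36, 1, 0.4))
  ch <- classify_change(p, f)
  s <- summarize_areas(ch, "toy")
  expect_equal(s$stable_km2 + s$loss_km2, s$present_km2, tolerance = 1e-12)
  expect_equal(s$present_km2, binary_area_km2(p), tolerance = 1e-12)
  total <- s$stable_km2 + s$gain_km2 + s$loss_km2 + s$unsuitable_km2
  rows_area <- pixel_area_km2(ch, 1:6)
  expect_equal(total, sum(rows_area * 6), tolerance = 1e-12)
  # identity future: no gain, no loss, stable = 100%
  s_id <- summarize_areas(classify_change(p, p), "identity")
  expect_equal(s_id$loss_km2, 0)
  expect_equal(s_id$gain_km2, 0)
  expect_equal(s_id$stable_pct, 100)
  # a future with zero present suitability is rejected
  z <- mk_map(0)
  expect_error(summarize_areas(classify_change(z, f), "none"),
               "present suitable area is zero")
})

test_that("printed-area accounting reproduces the published percentage arithmetic", {
  # losses of 6,928 km2 from an 11,432 km2 present area are 60.6%
  s <- change_summary_from_areas(stable_km2 = 4504, gain_km2 = 13485,
                                 loss_km2 = 6928)
  expect_equal(s$present_km2, 11432)
  expect_equal(round_half_up(s$loss_pct, 1), 60.6)
  expect_equal(round_half_up(s$stable_pct, 1), 39.4)
  expect_equal(round_half_up(s$gain_pct, 1), 118.0)
  # stable 4,895 + lost 8,347 imply a 13,242 km2 present area
  s2 <- change_summary_from_areas(stable_km2 = 4895, gain_km2 = 6126,
                                  loss_km2 = 8347)
  expect_equal(s2$present_km2, 13242)
  expect_equal(round_half_up(s2$stable_pct, 1), 37.0)
})

test_that("averaging across RCPs averages areas and reports both percentage styles", {
  a <- change_summary_from_areas(4895, 6126, 8347, scenario_id = "rcp45")
  b <- change_summary_from_areas(4559, 6085, 8683, scenario_id = "rcp85")
  avg <- average_scenarios(list(a, b))
  expect_equal(avg$gain_km2, (6126 + 6085) / 2)
  expect_equal(round_half_up(avg$gain_km2, 0), 6106)
  # report-parity mean uses the one-decimal percentages as printed
  expect_equal(avg$gain_pct_mean,
               mean(round_half_up(c(a$gain_pct, b$gain_pct), 1)))
  expect_equal(round_half_up(avg$gain_pct_mean, 1), 46.2)
  # identical summaries average to themselves
  same <- average_scenarios(list(a, a))
  expect_equal(same$stable_km2, a$stable_km2)
  expect_equal(same$loss_pct, a$loss_pct)
})

test_that("rounding in report tables is half-up", {
  expect_equal(round_half_up(46.15, 1), 46.2)
  expect_equal(round_half_up(36.85, 1), 36.9)
  expect_equal(round_half_up(6105.5, 0), 6106)
})

test_that("elevation bands partition category areas and expose upslope shifts", {
  set.seed(12)
  nr <- 20
  dem <- raster_grid(matrix(seq(3300, 7300, length.out = nr), nr, nr),
                     xmin = 72, ymax = 38, cellsize = 1 / 120, name = "dem")
  # construct: losses only below 4300 m, gains only above 5000 m
  loss_rows <- dem$values[, 1] < 4300
  gain_rows <- dem$values[, 1] > 5000
  p <- grid_like(dem, matrix(0, nr, nr))
  f <- grid_like(dem, matrix(0, nr, nr))
  p$values[loss_rows, ] <- 1
  f$values[gain_rows, ] <- 1
  p$values[10, ] <- 1; f$values[10, ] <- 1  # a stable band
  ch <- classify_change(p, f)
  bands <- elevation_band_summary(ch, dem, band_width_m = 200)
  low <- bands$bands$band_high_m <= 4400
  expect_equal(sum(bands$bands$loss_km2[!low]), 0)
  expect_gt(sum(bands$bands$loss_km2[low]), 0)
  # band areas sum to the total per-category areas
  s <- summarize_areas(ch)
  expect_equal(sum(bands$bands$loss_km2), s$loss_km2, tolerance = 1e-9)
  expect_equal(sum(bands$bands$gain_km2), s$gain_km2, tolerance = 1e-9)
  expect_equal(sum(bands$bands$stable_km2), s$stable_km2, tolerance = 1e-9)
  # gains sit higher than losses by construction
  expect_gt(bands$mean_elevation[["gain"]], bands$mean_elevation[["loss"]])
  expect_error(elevation_band_summary(ch, dem, 0), "band width")
})
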