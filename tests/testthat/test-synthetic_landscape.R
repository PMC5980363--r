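test_that("the DEM is deterministic, spans the configured range, and responds to correlation length", {
  cfg <- landscape_config(nrow = 50, ncol = 50, seed = 5)
  d1 <- generate_dem(cfg)
  d2 <- generate_dem(cfg)
  expect_identical(d1$values, d2$values)
  expect_equal(range(d1$values), c(3300, 7300))
  d3 <- generate_dem(landscape_config(nrow = 50, ncol = 50, seed = 6))
  expect_false(identical(d1$values, d3$values))
  # correlation length ~ grid width with no fine-scale relief or trend ->
  # near-planar relative to the default rugged setting (the elevation
  # envelope is always stretched to its endpoints, so the comparison is
  # relative, at a grid large enough to separate the scales)
  n <- 150
  smooth_cfg <- landscape_config(nrow = n, ncol = n, corr_len = n,
                                 roughness = 0, north_trend = 0, seed = 5)
  rough_cfg <- landscape_config(nrow = n, ncol = n, seed = 5)
  tri_smooth <- mean(tri(generate_dem(smooth_cfg))$values, na.rm = TRUE)
  tri_rough <- mean(tri(generate_dem(rough_cfg))$values, na.rm = TRUE)
  expect_lt(tri_smooth, 0.2 * tri_rough)
  # and mean ruggedness decreases monotonically with correlation length
  tris <- vapply(c(5, 20, 80), function(cl) {
    cfg_cl <- landscape_config(nrow = 80, ncol = 80, corr_len = cl,
                               roughness = 0, north_trend = 0, seed = 5)
    mean(tri(generate_dem(cfg_cl))$values, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(tris) < 0))
})

test_that("temperature follows the lapse rate and tracks elevation", {
  cfg <- landscape_config(nrow = 40, ncol = 40, climate_noise_sd = 0, seed = 9)
  dem <- generate_dem(cfg)
  clim <- generate_climate(dem, cfg)
  # zero noise: bio1 differences are exactly -6.5 C per km of elevation
  d_elev <- dem$values - dem$values[1, 1]
  d_temp <- clim$bio1$values - clim$bio1$values[1, 1]
  expect_equal(d_temp, -6.5 * d_elev / 1000, tolerance = 1e-12)
  # default noise: strong negative elevation-temperature correlation
  cfg2 <- landscape_config(nrow = 60, ncol = 60, seed = 11)
  dem2 <- generate_dem(cfg2)
  clim2 <- generate_climate(dem2, cfg2)
  expect_lt(cor(as.vector(clim2$bio1$values), as.vector(dem2$values)), -0.8)
  expect_identical(generate_climate(dem2, cfg2)$bio18$values,
                   clim2$bio18$values)
})

test_that("scenario deltas apply additively to temperature, multiplicatively to precipitation", {
  land <- fixture_landscape(40, seed = 3)$land
  st <- land$climate
  # identity delta
  id <- scenario_delta("null", temp_offset = 0, precip_factor = 1)
  out <- apply_scenario(st, id)
  for (nm in names(st)) expect_identical(out[[nm]]$values, st[[nm]]$values)
  # +2 C uniform with no noise
  d2 <- scenario_delta("warm2", temp_offset = 2, precip_factor = 1)
  out <- apply_scenario(st, d2)
  expect_equal(out$bio1$values, st$bio1$values + 2, tolerance = 1e-12)
  expect_equal(out$bio9$values, st$bio9$values + 2, tolerance = 1e-12)
  expect_identical(out$bio2$values, st$bio2$values)  # range layers untouched
  # x0.9 on precipitation
  d3 <- scenario_delta("dry", temp_offset = 0, precip_factor = 0.9)
  out <- apply_scenario(st, d3)
  expect_equal(out$bio18$values, st$bio18$values * 0.9, tolerance = 1e-12)
})

test_that("pseudo-GCMs share the pathway mean forcing", {
  land <- fixture_landscape(40, seed = 3)$land
  deltas <- gcm_deltas("rcp85", 2050, n_gcms = 4, seed = 77)
  expect_equal(vapply(deltas, `[[`, numeric(1), "temp_offset"),
               rep(2.5, 4))
  futs <- lapply(deltas, function(d) apply_scenario(land$climate, d))
  anom <- Reduce(`+`, lapply(futs, function(f) {
    f$bio1$values - land$climate$bio1$values
  })) / 4
  # cell-wise mean anomaly across GCMs approximates the common offset
  expect_lt(abs(mean(anom) - 2.5), 0.1)
  expect_lt(max(abs(anom - 2.5)), 4 * 0.3)
  # pathway ordering: 8.5 >= 4.5 and 2070 >= 2050
  for (h in c(2050, 2070)) {
    expect_gte(gcm_deltas("rcp85", h, seed = 1)[[1]]$temp_offset,
               gcm_deltas("rcp45", h, seed = 1)[[1]]$temp_offset)
  }
  for (r in c("rcp45", "rcp85")) {
    expect_gte(gcm_deltas(r, 2070, seed = 1)[[1]]$temp_offset,
               gcm_deltas(r, 2050, seed = 1)[[1]]$temp_offset)
  }
})

test_that("occurrence sampling follows the true suitability surface", {
  land <- fixture_landscape(60, seed = 42)$land
  st <- land$predictors
  # flat truth: mean suitability at points matches the grid mean
  flat_sp <- virtual_species(temp_opt = 0, temp_width = 1e9,
                             tri_scale = NULL, rip_decay_m = NULL)
  occ <- sample_occurrences(flat_sp, st, 800, seed = 4)
  expect_identical(nrow(occ), 800L)
  s <- attr(occ, "true_suitability")
  expect_gt(min(s$values, na.rm = TRUE), 0.999)
  # step-function truth: zero suitability excludes the region entirely
  st2 <- st
  north_zero <- st$bio1$values
  north_zero[31:60, ] <- -1e4  # far outside any niche
  st2$bio1 <- raster_grid(north_zero, st$bio1$xmin, st$bio1$ymax,
                          st$bio1$cellsize, name = "bio1")
  sp <- virtual_species(temp_opt = -8, temp_width = 2, tri_scale = NULL,
                        rip_decay_m = NULL)
  occ2 <- sample_occurrences(sp, st2, 300, seed = 5)
  lat_cut <- st$bio1$ymax - 30 * st$bio1$cellsize
  expect_true(all(occ2$lat > lat_cut))
  # determinism
  expect_identical(sample_occurrences(sp, st2, 50, seed = 6),
                   sample_occurrences(sp, st2, 50, seed = 6))
  expect_error(sample_occurrences(virtual_species(temp_opt = 1e6), st, 10,
                                  seed = 1),
               "zero everywhere")
})

test_that("a Gaussian temperature niche is recovered by the sampled points", {
  # symmetric temperature availability around the optimum isolates the
  # sampler from availability bias
  set.seed(31)
  f <- gaussian_field(80, 80, 10, seed = 31)
  bio1 <- raster_grid(-8 + 5 * f, xmin = 72, ymax = 39, cellsize = 1 / 120,
                      name = "bio1")
  st <- raster_stack(list(bio1))
  sp <- virtual_species(temp_opt = -8, temp_width = 2, tri_scale = NULL,
                        rip_decay_m = NULL)
  occ <- sample_occurrences(sp, st, 1000, seed = 8)
  idx <- cell_index(bio1, occ$lon, occ$lat)
  temps <- bio1$values[cbind(idx$row, idx$col)]
  expect_lt(abs(mean(temps) - (-8)), 0.5)
})

test_that("riparian masks are binary with the configured areal fraction", {
  fx <- fixture_landscape(60, seed = 42)
  rip <- fx$land$riparian
  expect_true(all(rip$values %in% c(0, 1)))
  expect_equal(mean(rip$values), fx$config$riparian_frac, tolerance = 0.01)
})
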