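# Virtual mountainous landscape: correlated random fields for the DEM,
# elevation-coupled bioclim layers, a riparian network, pseudo-GCM scenario
# deltas, and a virtual species with known truth.

#' Landscape generator configuration
#'
#' Defaults describe a high-mountain study region: a 300 x 300 grid of
#' 30 arc-second cells (about 2.5 degrees on a side) with elevations spanning
#' 3,300-7,300 m and a north-south trend so the northern half is higher.
#'
#' @param nrow,ncol Grid dimensions.
#' @param cellsize Cell size in degrees (default 30 arc-sec = 1/120 degree).
#' @param xmin,ymax Western / northern grid edges (degrees).
#' @param elev_range Elevation envelope in meters, ordered `c(min, max)`.
#' @param corr_len Spatial correlation length of the random fields, in cells.
#' @param north_trend Weight of the north-south elevation gradient relative
#'   to one standard deviation of the random field.
#' @param roughness Amplitude of the fine-scale relief component (relative
#'   to one s.d. of the base field); 0 gives a smooth surface with no steep
#'   escape terrain.
#' @param rough_len Correlation length of the fine-scale component, cells.
#' @param t0 Sea-level annual mean temperature (deg C) for the lapse model.
#' @param lapse_rate Temperature lapse rate in deg C per km (positive value
#'   means cooling with elevation).
#' @param climate_noise_sd Std. dev. (deg C) of the correlated noise added to
#'   the temperature layers.
#' @param riparian_frac Fraction of cells in the riparian network.
#' @param seed Integer seed; mandatory for every stochastic draw.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(nrow = 300, ncol = 300, cellsize = 1 / 120,
                             xmin = 72.5, ymax = 39.5,
                             elev_range = c(3300, 7300), corr_len = 40,
                             north_trend = 1.2, roughness = 1.0,
                             rough_len = 1.2, t0 = 20, lapse_rate = 6.5,
                             climate_noise_sd = 0.5, riparian_frac = 0.07,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (length(elev_range) != 2 || diff(elev_range) <= 0) {
    stop("elev_range must be an increasing pair")
  }
  if (corr_len <= 0) stop("correlation length must be positive")
  structure(list(nrow = nrow, ncol = ncol, cellsize = cellsize, xmin = xmin,
                 ymax = ymax, elev_range = elev_range, corr_len = corr_len,
                 north_trend = north_trend, roughness = roughness,
                 rough_len = rough_len, t0 = t0, lapse_rate = lapse_rate,
                 climate_noise_sd = climate_noise_sd,
                 riparian_frac = riparian_frac, seed = as.integer(seed)),
            class = "landscape_config")
}

#' Correlated Gaussian random field
#'
#' White noise convolved with a Gaussian kernel of scale `corr_len` cells via
#' FFT (circulant boundary), then standardized to zero mean and unit
#' variance. Deterministic given the seed.
#'
#' @param nrow,ncol Field dimensions.
#' @param corr_len Correlation length in cells, > 0.
#' @param seed Integer seed.
#' @return A numeric matrix.
#' @export
gaussian_field <- function(nrow, ncol, corr_len, seed) {
  if (corr_len <= 0) stop("correlation length must be positive")
  set.seed(seed)
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  fx <- c(0:floor(ncol / 2), -(ceiling(ncol / 2) - 1):-1) / ncol
  fy <- c(0:floor(nrow / 2), -(ceiling(nrow / 2) - 1):-1) / nrow
  h <- outer(exp(-2 * pi^2 * corr_len^2 * fy^2),
             exp(-2 * pi^2 * corr_len^2 * fx^2))
  f <- Re(stats::fft(stats::fft(z) * h, inverse = TRUE)) / (nrow * ncol)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a mountainous DEM
#'
#' A correlated random field plus a north-south gradient, linearly rescaled
#' into the configured elevation envelope, so the output min/max equal the
#' envelope endpoints exactly.
#'
#' @param config A `landscape_config`.
#' @return A `raster_grid` named `"dem"`, in meters.
#' @export
generate_dem <- function(config) {
  f <- gaussian_field(config$nrow, config$ncol, config$corr_len, config$seed)
  trend <- matrix(rev(seq_len(config$nrow)), config$nrow, config$ncol)
  trend <- (trend - mean(trend)) / stats::sd(trend)  # higher in the north
  raw <- f + config$north_trend * trend
  if (config$roughness > 0) {
    # fine-scale relief (gorges, ridges) so steep escape terrain exists at
    # ~900 m cells, as in real mountain DEMs
    raw <- raw + config$roughness *
      gaussian_field(config$nrow, config$ncol, config$rough_len,
                     config$seed + 1L)
  }
  rng <- range(raw)
  elev <- config$elev_range[1] +
    (raw - rng[1]) / diff(rng) * diff(config$elev_range)
  raster_grid(elev, xmin = config$xmin, ymax = config$ymax,
              cellsize = config$cellsize, name = "dem")
}

# layer classification used when applying scenario deltas
ABS_TEMP_LAYERS <- c("bio1", "bio5", "bio6", "bio8", "bio9", "bio10", "bio11")
PRECIP_LAYERS <- paste0("bio", 12:19)

#' Generate bioclim-style climate layers from a DEM
#'
#' Emulates the asterisked WorldClim set used for mountain-ungulate habitat
#' modeling: annual mean temperature (bio1) follows the configured lapse rate
#' (default -6.5 deg C per km of elevation) plus correlated noise; mean
#' temperature of the driest quarter (bio9) tracks bio1; diurnal range
#' (bio2), isothermality (bio3), temperature seasonality (bio4), and
#' precipitation seasonality (bio15) are spatially structured fields;
#' precipitation of the warmest quarter (bio18) increases orographically
#' with elevation.
#'
#' @param dem DEM `raster_grid` in meters.
#' @param config The `landscape_config` used to build the DEM.
#' @return A `raster_stack` with layers
#'   `bio1, bio2, bio3, bio4, bio9, bio15, bio18`.
#' @export
generate_climate <- function(dem, config) {
  nr <- grid_nrow(dem); nc <- grid_ncol(dem)
  fld <- function(off) gaussian_field(nr, nc, config$corr_len / 2,
                                      config$seed + off)
  nsd <- config$climate_noise_sd
  bio1 <- config$t0 - config$lapse_rate * dem$values / 1000 + nsd * fld(101L)
  bio2 <- 14 + 1.5 * fld(102L)
  bio3 <- 35 + 3 * fld(103L)
  bio4 <- 900 + 80 * fld(104L)
  bio9 <- bio1 - 3 + nsd * fld(109L)
  bio15 <- 80 + 8 * fld(115L)
  bio18 <- pmax(60 + 0.008 * dem$values + 15 * fld(118L), 5)
  mk <- function(v, nm) grid_like(dem, v, nm)
  raster_stack(list(mk(bio1, "bio1"), mk(bio2, "bio2"), mk(bio3, "bio3"),
                    mk(bio4, "bio4"), mk(bio9, "bio9"), mk(bio15, "bio15"),
                    mk(bio18, "bio18")))
}

#' Generate a riparian network mask
#'
#' Thresholds an independent smoothed random field at the configured areal
#' fraction, yielding a connected, sinuous network of valley-like cells --
#' a stand-in for mapped riparian areas.
#'
#' @param dem DEM `raster_grid` (supplies the geometry).
#' @param config A `landscape_config`.
#' @return A binary `raster_grid` named `"riparian"`.
#' @export
generate_riparian <- function(dem, config) {
  f <- gaussian_field(grid_nrow(dem), grid_ncol(dem), config$corr_len / 4,
                      config$seed + 7L)
  cut <- stats::quantile(f, 1 - config$riparian_frac)
  grid_like(dem, ifelse(f >= cut, 1, 0), "riparian")
}

#' Define a virtual species
#'
#' Known truth for pipeline validation: suitability is the product of a
#' generalized-Gaussian response to annual mean temperature (the planted
#' primary driver, spanning the full 0-1 range; the default exponent 4
#' gives a flat-topped plateau with steep shoulders) and two bounded secondary
#' modifiers -- an increasing logistic response to terrain ruggedness and
#' an exponential decay with distance to riparian areas -- each floored
#' below 1 so they modulate rather than exclude. Suitability therefore
#' stays in `[0, 1]` with a genuine high-suitability core (cells above
#' 0.5) wherever the temperature is near the optimum.
#'
#' @param temp_opt Temperature optimum (deg C) on `bio1`.
#' @param temp_width Niche width (deg C) of the temperature response.
#' @param temp_shape Exponent of the generalized-Gaussian temperature
#'   response: 2 is the classic Gaussian, the default 4 a plateau.
#' @param tri_mid,tri_scale Logistic midpoint/scale on `tri` (meters); set
#'   `tri_scale = NULL` to drop the ruggedness factor.
#' @param tri_floor Lower bound of the ruggedness modifier in `[0, 1)`.
#' @param rip_decay_m e-folding distance (m) on `dist_riparian`; `NULL`
#'   drops the factor.
#' @param rip_floor Lower bound of the riparian modifier in `[0, 1)`.
#' @return A `virtual_species` object with a `drivers` field naming the
#'   predictor layers the truth depends on.
#' @export
virtual_species <- function(temp_opt = -8, temp_width = 2, temp_shape = 4,
                            tri_mid = 150,
                            tri_scale = 60, tri_floor = 0.5,
                            rip_decay_m = 25000, rip_floor = 0.6) {
  drivers <- "bio1"
  if (!is.null(tri_scale)) drivers <- c(drivers, "tri")
  if (!is.null(rip_decay_m)) drivers <- c(drivers, "dist_riparian")
  structure(list(temp_opt = temp_opt, temp_width = temp_width,
                 temp_shape = temp_shape,
                 tri_mid = tri_mid, tri_scale = tri_scale,
                 tri_floor = tri_floor, rip_decay_m = rip_decay_m,
                 rip_floor = rip_floor, drivers = drivers),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' The response product is rescaled by its maximum over the landscape's
#' valid cells (the usual min-max convention for virtual species), so the
#' best available habitat scores 1 and "suitability at least 0.5" reads as
#' "within half of the best cell". Rescaling is monotone, so occurrence
#' sampling probabilities and rank-based scores are unaffected.
#'
#' @param species A `virtual_species`.
#' @param stack A `raster_stack` containing the species' driver layers.
#' @param rescale Normalize the maximum to 1 (default TRUE).
#' @return A `raster_grid` of suitabilities in `[0, 1]`.
#' @export
true_suitability <- function(species, stack, rescale = TRUE) {
  missing <- setdiff(species$drivers, names(stack))
  if (length(missing)) {
    stop("stack lacks driver layer(s): ", paste(missing, collapse = ", "))
  }
  shape <- species$temp_shape %||% 2
  s <- exp(-0.5 * abs((stack$bio1$values - species$temp_opt) /
                        species$temp_width)^shape)
  if (!is.null(species$tri_scale)) {
    s <- s * (species$tri_floor + (1 - species$tri_floor) *
                stats::plogis((stack$tri$values - species$tri_mid) /
                                species$tri_scale))
  }
  if (!is.null(species$rip_decay_m)) {
    s <- s * (species$rip_floor + (1 - species$rip_floor) *
                exp(-stack$dist_riparian$values / species$rip_decay_m))
  }
  if (rescale && any(is.finite(s)) && max(s, na.rm = TRUE) > 0) {
    s <- s / max(s, na.rm = TRUE)
  }
  grid_like(stack[[1]], s, "true_suitability")
}

#' Sample presence points from a virtual species
#'
#' Draws `n` presence points with probability proportional to true
#' suitability: cells are sampled with replacement (so clustered, multi-point
#' cells occur, as in field sighting data) and each point is jittered
#' uniformly within its cell.
#'
#' @param species A `virtual_species`.
#' @param stack Stack containing the species' drivers.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return Data frame with columns `lon`, `lat` and attribute
#'   `"true_suitability"` (grid used for sampling).
#' @export
sample_occurrences <- function(species, stack, n, seed) {
  s <- true_suitability(species, stack)
  w <- as.vector(s$values)
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("true suitability is zero everywhere")
  set.seed(seed)
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  g <- s
  nr <- grid_nrow(g)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  lon <- g$xmin + (col - 1L + stats::runif(n)) * g$cellsize
  lat <- g$ymax - (row - 1L + stats::runif(n)) * g$cellsize
  out <- data.frame(lon = lon, lat = lat)
  attr(out, "true_suitability") <- s
  out
}

#' Pseudo-GCM scenario delta
#'
#' An additive, spatially uniform warming offset applied to absolute
#' temperature layers, a multiplicative factor applied to precipitation
#' layers, and seeded correlated inter-GCM noise emulating disagreement
#' between climate models.
#'
#' @param id Scenario label (e.g. `"gcm1_rcp45_2050"`).
#' @param temp_offset Warming in deg C.
#' @param precip_factor Multiplicative precipitation change.
#' @param noise_sd_temp Std. dev. (deg C) of the correlated temperature
#'   noise field; 0 disables it.
#' @param noise_sd_precip Std. dev. of the multiplicative precipitation
#'   noise (as a fraction); 0 disables it.
#' @param seed Integer seed for the noise fields.
#' @return A `scenario_delta` object.
#' @export
scenario_delta <- function(id, temp_offset, precip_factor = 1,
                           noise_sd_temp = 0, noise_sd_precip = 0, seed = 1L) {
  structure(list(id = id, temp_offset = temp_offset,
                 precip_factor = precip_factor,
                 noise_sd_temp = noise_sd_temp,
                 noise_sd_precip = noise_sd_precip,
                 seed = as.integer(seed)),
            class = "scenario_delta")
}

# default emission-pathway offsets; 8.5 >= 4.5 and 2070 >= 2050 within RCP
default_scenario_table <- function() {
  data.frame(
    rcp = c("rcp45", "rcp45", "rcp85", "rcp85"),
    horizon = c(2050, 2070, 2050, 2070),
    temp_offset = c(1.5, 2.0, 2.5, 4.0),
    precip_factor = c(0.95, 0.93, 0.90, 0.85))
}

#' Build the pseudo-GCM deltas for one RCP x horizon scenario
#'
#' All GCMs share the pathway's mean offset and differ only through seeded
#' correlated noise, mimicking inter-model disagreement around a common
#' forcing.
#'
#' @param rcp `"rcp45"` or `"rcp85"`.
#' @param horizon 2050 or 2070.
#' @param n_gcms Number of pseudo-GCMs (default 4).
#' @param noise_sd_temp,noise_sd_precip Inter-GCM noise scales.
#' @param seed Base seed; GCM `i` uses `seed + i`.
#' @return List of `scenario_delta` objects, one per GCM.
#' @export
gcm_deltas <- function(rcp = c("rcp45", "rcp85"), horizon = 2050, n_gcms = 4,
                       noise_sd_temp = 0.3, noise_sd_precip = 0.04,
                       seed = 1L) {
  rcp <- match.arg(rcp)
  tab <- default_scenario_table()
  row <- tab[tab$rcp == rcp & tab$horizon == horizon, ]
  if (nrow(row) != 1) stop("unknown scenario: ", rcp, " ", horizon)
  lapply(seq_len(n_gcms), function(i) {
    scenario_delta(id = sprintf("gcm%d_%s_%d", i, rcp, horizon),
                   temp_offset = row$temp_offset,
                   precip_factor = row$precip_factor,
                   noise_sd_temp = noise_sd_temp,
                   noise_sd_precip = noise_sd_precip,
                   seed = seed + i)
  })
}

#' Apply a scenario delta to a climate stack
#'
#' Absolute temperature layers (`bio1`, `bio5`, `bio6`, `bio8`-`bio11`) are
#' shifted additively; precipitation layers (`bio12`-`bio19`) are scaled
#' multiplicatively (floored at 0); other layers pass through unchanged.
#' Seeded correlated noise is added per affected layer when the delta's
#' noise scales are nonzero.
#'
#' @param stack Present-day `raster_stack`.
#' @param delta A `scenario_delta`.
#' @return A future `raster_stack` on the same grid.
#' @export
apply_scenario <- function(stack, delta) {
  nr <- grid_nrow(stack[[1]]); nc <- grid_ncol(stack[[1]])
  corr <- max(4, round(min(nr, nc) / 8))
  out <- stack
  k <- 0L
  for (nm in names(stack)) {
    g <- stack[[nm]]
    if (nm %in% ABS_TEMP_LAYERS) {
      k <- k + 1L
      v <- g$values + delta$temp_offset
      if (delta$noise_sd_temp > 0) {
        v <- v + delta$noise_sd_temp *
          gaussian_field(nr, nc, corr, delta$seed * 131L + k)
      }
      out[[nm]] <- grid_like(g, v)
    } else if (nm %in% PRECIP_LAYERS || nm %in% c("bio15", "bio18")) {
      k <- k + 1L
      fac <- delta$precip_factor
      if (delta$noise_sd_precip > 0) {
        fac <- fac * (1 + delta$noise_sd_precip *
                        gaussian_field(nr, nc, corr, delta$seed * 131L + k))
      }
      out[[nm]] <- grid_like(g, pmax(g$values * fac, 0))
    }
  }
  out
}

#' Generate the complete synthetic landscape
#'
#' Convenience wrapper producing the DEM, climate stack, riparian mask,
#' terrain predictors, and the combined predictor stack used for modeling.
#'
#' @param config A `landscape_config`.
#' @param slope_threshold_deg Escape-terrain slope threshold (degrees).
#' @return List with elements `dem`, `climate`, `riparian`, `terrain`, and
#'   `predictors` (climate + terrain combined `raster_stack`).
#' @export
generate_landscape <- function(config, slope_threshold_deg = 30) {
  dem <- generate_dem(config)
  climate <- generate_climate(dem, config)
  riparian <- generate_riparian(dem, config)
  terrain <- terrain_predictors(dem, riparian, slope_threshold_deg)
  predictors <- raster_stack(c(unclass(climate), unclass(terrain)))
  list(dem = dem, climate = climate, riparian = riparian, terrain = terrain,
       predictors = predictors)
}
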