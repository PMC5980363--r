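# Nonclimatic predictors derived from the DEM: Horn slope/aspect, terrain
# ruggedness index (TRI), and Euclidean distance to cell classes (escape
# terrain, riparian areas).

# ground cell sizes in meters; dx varies with row latitude on lon/lat grids
ground_res_m <- function(g) {
  dy <- g$cellsize * KM_PER_DEG * 1000
  dx <- dy * cos(grid_lats(g) * pi / 180)
  list(dx = dx, dy = dy)
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

#' Slope and aspect from a DEM (Horn's method)
#'
#' Finite differences over the 8 neighbors of each cell (Horn kernel), with
#' degree cell sizes converted to meters at each row's latitude. Slope is
#' percent rise; aspect is the downslope direction in degrees clockwise from
#' north. Flat cells (zero gradient) have nodata aspect. Border cells are
#' nodata.
#'
#' @param dem A `raster_grid` of elevations in meters, at least 3x3.
#' @return List with elements `slope` (percent) and `aspect` (degrees).
#' @export
slope_aspect <- function(dem) {
  m <- dem$values
  if (nrow(m) < 3 || ncol(m) < 3) stop("DEM smaller than the 3x3 window")
  res <- ground_res_m(dem)
  # 8 neighbors; row -1 = north
  nw <- shift_mat(m, -1, -1); n_ <- shift_mat(m, -1, 0); ne <- shift_mat(m, -1, 1)
  w_ <- shift_mat(m, 0, -1);                             e_ <- shift_mat(m, 0, 1)
  sw <- shift_mat(m, 1, -1);  s_ <- shift_mat(m, 1, 0);  se <- shift_mat(m, 1, 1)
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * res$dx)  # per row
  dzdy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * res$dy)  # northward
  slope <- 100 * sqrt(dzdx^2 + dzdy^2)
  # azimuth of the downslope vector (-dzdx east, -dzdy north)
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[!is.na(slope) & slope == 0] <- NA_real_
  list(slope = grid_like(dem, slope, "slope"),
       aspect = grid_like(dem, aspect, "aspect"))
}

#' Northness and eastness from aspect
#'
#' Cosine and sine of aspect, a non-circular encoding suitable for modeling.
#' Flat (nodata-aspect) cells are 0 in both components when the slope layer
#' marks them flat, otherwise nodata propagates.
#'
#' @param aspect Aspect `raster_grid` in degrees.
#' @param slope Optional slope `raster_grid`; cells with slope 0 get 0.
#' @return List with `northness` and `eastness` grids in `[-1, 1]`.
#' @export
aspect_components <- function(aspect, slope = NULL) {
  rad <- aspect$values * pi / 180
  nor <- cos(rad); eas <- sin(rad)
  if (!is.null(slope)) {
    flat <- slope$values == 0 & !is.na(slope$values)
    nor[flat] <- 0; eas[flat] <- 0
  }
  list(northness = grid_like(aspect, nor, "northness"),
       eastness = grid_like(aspect, eas, "eastness"))
}

#' Terrain ruggedness index
#'
#' Mean absolute elevation difference between each cell and its 8 neighbors
#' in a 3x3 window. Border cells (incomplete window) are nodata, as is any
#' cell whose window touches nodata.
#'
#' @param dem A `raster_grid` of elevations.
#' @return A `raster_grid` named `"tri"`.
#' @export
tri <- function(dem) {
  m <- dem$values
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + abs(shift_mat(m, dr, dc) - m)
  }
  grid_like(dem, acc / 8, "tri")
}

# Felzenszwalb-Huttenlocher 1-D squared distance transform.
# f: squared distances (Inf where no site); returns lower envelope sampled
# at 1..n (grid units).
edt_1d <- function(f) {
  n <- length(f)
  sites <- which(is.finite(f))
  if (!length(sites)) return(rep(Inf, n))
  v <- integer(length(sites)); z <- numeric(length(sites) + 1)
  k <- 1L; v[1] <- sites[1]; z[1] <- -Inf; z[2] <- Inf
  if (length(sites) > 1L) {
    for (q in sites[-1]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + q^2) - (f[p] + p^2)) / (2 * q - 2 * p)
        if (k > 1L && s <= z[k]) k <- k - 1L else break
      }
      k <- k + 1L
      v[k] <- q; z[k] <- s; z[k + 1] <- Inf
    }
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance to a cell class
#'
#' Distance in meters from every cell center to the nearest center of a
#' `TRUE` cell of the mask (0 inside the class). Computed with the exact
#' two-pass Felzenszwalb-Huttenlocher transform on a local equirectangular
#' projection (east-west meters per degree evaluated at the grid's mean
#' latitude).
#'
#' @param mask A `raster_grid` whose values are interpreted as logical
#'   (nonzero/`TRUE` = in class); must contain at least one `TRUE` cell.
#' @return A `raster_grid` of distances in meters.
#' @export
distance_to_class <- function(mask) {
  inm <- mask$values
  inside <- !is.na(inm) & inm != 0
  if (!any(inside)) stop("empty mask: no cells in the target class")
  nr <- nrow(inm); nc <- ncol(inm)
  dy <- mask$cellsize * KM_PER_DEG * 1000
  dx <- dy * cos(mean(grid_lats(mask)) * pi / 180)
  # pass 1: columns (units of dy)
  f <- matrix(Inf, nr, nc)
  f[inside] <- 0
  for (j in seq_len(nc)) f[, j] <- edt_1d(f[, j])
  # convert row-direction squared units to meters^2, then scan rows in dx units
  f <- f * dy^2 / dx^2
  for (i in seq_len(nr)) f[i, ] <- edt_1d(f[i, ])
  grid_like(mask, sqrt(f) * dx, paste0("dist_", mask$name))
}

#' Distance to escape terrain
#'
#' Escape terrain is the set of cells with slope at or above a threshold
#' (default 30 degrees); the result is the Euclidean distance in meters to
#' the nearest such cell.
#'
#' @param dem A `raster_grid` of elevations.
#' @param slope_threshold_deg Slope threshold in degrees, in (0, 90).
#' @return A `raster_grid` named `"dist_escape"`.
#' @export
escape_terrain_distance <- function(dem, slope_threshold_deg = 30) {
  if (slope_threshold_deg <= 0 || slope_threshold_deg >= 90) {
    stop("slope threshold must be in (0, 90) degrees")
  }
  sl <- slope_aspect(dem)$slope
  pct <- 100 * tan(slope_threshold_deg * pi / 180)
  mask <- grid_like(sl, ifelse(!is.na(sl$values) & sl$values >= pct, 1, 0),
                    "escape")
  out <- distance_to_class(mask)
  out$name <- "dist_escape"
  out
}

#' Assemble the terrain predictor stack
#'
#' Derives `tri`, `slope`, `aspect` (or `northness`/`eastness`),
#' `dist_escape`, and `dist_riparian` from a DEM and a riparian mask.
#'
#' @param dem A `raster_grid` of elevations in meters.
#' @param riparian Binary `raster_grid` marking riparian cells.
#' @param slope_threshold_deg Escape-terrain slope threshold (degrees).
#' @param aspect_encoding `"components"` (northness/eastness, default) or
#'   `"degrees"` (raw circular aspect).
#' @return A `raster_stack` of terrain predictors.
#' @export
terrain_predictors <- function(dem, riparian, slope_threshold_deg = 30,
                               aspect_encoding = c("components", "degrees")) {
  aspect_encoding <- match.arg(aspect_encoding)
  sa <- slope_aspect(dem)
  rip <- distance_to_class(riparian)
  rip$name <- "dist_riparian"
  layers <- list(tri(dem), sa$slope)
  if (aspect_encoding == "components") {
    ac <- aspect_components(sa$aspect, sa$slope)
    layers <- c(layers, list(ac$northness, ac$eastness))
  } else {
    layers <- c(layers, list(sa$aspect))
  }
  c_layers <- c(layers, list(
    escape_terrain_distance(dem, slope_threshold_deg), rip))
  raster_stack(c_layers)
}
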