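# Occurrence cleaning (one point per pixel), 70/30 train/test splitting, and
# background (pseudo-absence) sampling inside a 95% minimum convex polygon.

#' Thin occurrences to one point per grid cell
#'
#' Clustered sightings introduce spatial bias; thinning keeps the first point
#' (input order) in every occupied cell and discards the rest, so results
#' are reproducible for a fixed input file.
#'
#' @param points Data frame with columns `lon`, `lat`.
#' @param grid `raster_grid` defining the pixel geometry.
#' @return Data frame `lon`, `lat` with attribute `"n_removed"`; at most one
#'   point per cell. Points outside the grid are dropped first.
#' @export
thin_per_pixel <- function(points, grid) {
  if (!nrow(points)) stop("empty occurrence set")
  idx <- cell_index(grid, points$lon, points$lat)
  inside <- !is.na(idx$row)
  pts <- points[inside, , drop = FALSE]
  key <- paste(idx$row[inside], idx$col[inside])
  keep <- !duplicated(key)
  out <- pts[keep, c("lon", "lat"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- nrow(points) - nrow(out)
  out
}

#' Split occurrences into training and testing subsets
#'
#' Uniform random partition without replacement; the training set size is
#' `floor(fraction * n)`. Deterministic given the seed.
#'
#' @param occ Data frame with columns `lon`, `lat` (thinned occurrences).
#' @param fraction Training fraction (default 0.70).
#' @param seed Integer seed.
#' @return The input with an added `role` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(occ, fraction = 0.70, seed) {
  n <- nrow(occ)
  if (n < 10) stop("need at least 10 thinned points to split")
  n_train <- floor(fraction * n)
  set.seed(seed)
  train_idx <- sample.int(n, n_train)
  occ$role <- "test"
  occ$role[train_idx] <- "train"
  rownames(occ) <- NULL
  occ
}

# is each point inside (or on the boundary of) a counter-clockwise convex
# polygon? Cross-product sign test.
in_convex_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    inside <- inside & cross >= -1e-12
  }
  inside
}

#' Minimum convex polygon of presence points
#'
#' The `retain` fraction (default 95%) of points closest to the presence
#' centroid (Euclidean distance in degrees) is kept -- `ceil(retain * n)`
#' points -- and the convex hull of the kept points is returned.
#'
#' @param occ Data frame with columns `lon`, `lat`.
#' @param retain Fraction of points to keep before taking the hull.
#' @return Data frame of hull vertices (`lon`, `lat`), counter-clockwise.
#' @export
mcp_polygon <- function(occ, retain = 0.95) {
  if (nrow(occ) < 5) stop("need at least 5 presence points for an MCP")
  cx <- mean(occ$lon); cy <- mean(occ$lat)
  d <- sqrt((occ$lon - cx)^2 + (occ$lat - cy)^2)
  keep_n <- ceiling(retain * nrow(occ))
  kept <- occ[order(d)[seq_len(keep_n)], , drop = FALSE]
  hull_idx <- grDevices::chull(kept$lon, kept$lat)
  hull <- kept[hull_idx, c("lon", "lat"), drop = FALSE]
  if (nrow(hull) < 3) stop("degenerate (collinear) convex hull")
  # normalize to counter-clockwise (shoelace signed area)
  x <- hull$lon; y <- hull$lat
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (area2 < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  rownames(hull) <- NULL
  hull
}

#' WKT representation of an MCP polygon
#' @param hull Data frame of hull vertices (`lon`, `lat`).
#' @return A `POLYGON ((...))` WKT string (ring closed).
#' @export
mcp_wkt <- function(hull) {
  ring <- rbind(hull, hull[1, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.10g %.10g", ring$lon, ring$lat), collapse = ", "))
}

#' Sample background (pseudo-absence) points inside a 95% MCP
#'
#' Rejection-samples uniform points inside the minimum convex polygon of the
#' retained presence points, keeping only points that fall on valid
#' (non-nodata) cells of the reference grid.
#'
#' @param occ Presence data frame (`lon`, `lat`).
#' @param grid Reference `raster_grid` supplying the valid-cell mask.
#' @param n_background Number of background points (default 10,000).
#' @param retain MCP retain fraction (default 0.95).
#' @param seed Integer seed.
#' @return List with `points` (data frame `lon`, `lat`), `hull` (vertex data
#'   frame), and `wkt`.
#' @export
mcp_background <- function(occ, grid, n_background = 10000, retain = 0.95,
                           seed) {
  hull <- mcp_polygon(occ, retain)
  set.seed(seed)
  xr <- range(hull$lon); yr <- range(hull$lat)
  got <- matrix(numeric(0), ncol = 2)
  guard <- 0L
  while (nrow(got) < n_background) {
    guard <- guard + 1L
    if (guard > 1000L) stop("background rejection sampling failed to converge")
    m <- max(2L * (n_background - nrow(got)), 100L)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    ok <- in_convex_polygon(px, py, hull$lon, hull$lat)
    if (any(ok)) {
      idx <- cell_index(grid, px[ok], py[ok])
      valid <- !is.na(idx$row) &
        !is.na(grid$values[cbind(idx$row, idx$col)])
      got <- rbind(got, cbind(px[ok][valid], py[ok][valid]))
    }
  }
  pts <- data.frame(lon = got[seq_len(n_background), 1],
                    lat = got[seq_len(n_background), 2])
  list(points = pts, hull = hull, wkt = mcp_wkt(hull))
}
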