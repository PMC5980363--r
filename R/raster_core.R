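# Lightweight geographic raster container and ESRI ASCII Grid I/O.
#
# Grids are north-up (row 1 = northernmost row), cell-center registered,
# lon/lat only. Missing cells are stored as NA internally; the nodata
# sentinel exists only on disk.

KM_PER_DEG <- 111.195  # 40,030.2 km Earth circumference / 360

#' Construct a raster grid
#'
#' A `raster_grid` is a rectangular matrix of cell values on a regular
#' geographic (lon/lat) grid. Row 1 is the northernmost row; cells are
#' center-registered. Missing cells are `NA`.
#'
#' @param values Numeric matrix, rows ordered north to south.
#' @param xmin Western edge (degrees longitude) of the westernmost column.
#' @param ymax Northern edge (degrees latitude) of the northernmost row.
#' @param cellsize Cell size in decimal degrees (square cells), > 0.
#' @param crs Coordinate reference identifier (default `"EPSG:4326"`).
#' @param name Layer label.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin, ymax, cellsize, crs = "EPSG:4326",
                        name = "layer") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (!is.finite(cellsize) || cellsize <= 0) stop("cellsize must be > 0")
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         cellsize = as.numeric(cellsize), crs = crs, name = name),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "raster_grid '%s': %d x %d cells, res %.6g deg, x [%.6g, %.6g], y [%.6g, %.6g]\n",
    x$name, nrow(x$values), ncol(x$values), x$cellsize,
    x$xmin, x$xmin + ncol(x$values) * x$cellsize,
    x$ymax - nrow(x$values) * x$cellsize, x$ymax))
  if (length(v)) {
    cat(sprintf("  values: min %.6g, mean %.6g, max %.6g (%d nodata)\n",
                min(v), mean(v), max(v), sum(!is.finite(x$values))))
  } else cat("  all nodata\n")
  invisible(x)
}

grid_nrow <- function(g) nrow(g$values)
grid_ncol <- function(g) ncol(g$values)
grid_ymin <- function(g) g$ymax - grid_nrow(g) * g$cellsize
grid_xmax <- function(g) g$xmin + grid_ncol(g) * g$cellsize

# cell-center coordinates
grid_lons <- function(g) g$xmin + (seq_len(grid_ncol(g)) - 0.5) * g$cellsize
grid_lats <- function(g) g$ymax - (seq_len(grid_nrow(g)) - 0.5) * g$cellsize

#' Do two grids share shape, transform, and CRS?
#' @param a,b `raster_grid` objects.
#' @param tol Numeric tolerance on the transform, in degrees.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cellsize - b$cellsize) < tol && identical(a$crs, b$crs)
}

#' Locate points on a grid
#'
#' Maps lon/lat points to (row, col) indices. Cell membership uses half-open
#' intervals `[west, east)` in longitude and `(south, north]` in latitude, so
#' every point belongs to at most one cell. Points outside the extent get NA.
#'
#' @param g A `raster_grid`.
#' @param lon,lat Numeric coordinate vectors.
#' @return Data frame with columns `row`, `col` (NA when outside the grid).
#' @export
cell_index <- function(g, lon, lat) {
  col <- floor((lon - g$xmin) / g$cellsize) + 1L
  row <- floor((g$ymax - lat) / g$cellsize) + 1L
  # latitude exactly on the northern edge belongs to row 1
  row[lat == g$ymax] <- 1L
  bad <- col < 1L | col > grid_ncol(g) | row < 1L | row > grid_nrow(g)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Read an ESRI ASCII Grid file
#'
#' Parses the plain-text ArcInfo ASCII raster format (6-line header followed
#' by whitespace-separated cell values, rows north to south). Cells equal to
#' the file's `NODATA_value` become `NA`.
#'
#' @param path File path.
#' @param name Layer label; defaults to the file name without extension.
#' @param crs CRS identifier to record.
#' @return A `raster_grid`.
#' @export
read_asc <- function(path, name = NULL, crs = "EPSG:4326") {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated ASCII grid header in ", path)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (suppressWarnings(!is.na(as.numeric(key)))) { seek(con, pos); break }
    hdr[[key]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("missing header fields in ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2
         else stop("missing x origin in ", path)
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2
         else stop("missing y origin in ", path)
  vals <- scan(con, what = double(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raster_grid(m, xmin = xll, ymax = yll + nr * cs, cellsize = cs,
              crs = crs, name = name)
}

#' Write a grid as an ESRI ASCII Grid file
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces doubles exactly. `NA` cells are written as the nodata sentinel.
#'
#' @param g A `raster_grid`.
#' @param path Output file path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(g, path, nodata = -9999) {
  m <- g$values
  if (any(is.finite(m) & m == nodata)) {
    stop("grid contains cells equal to the nodata sentinel ", nodata)
  }
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.17g", g$xmin),
    sprintf("yllcorner %.17g", grid_ymin(g)),
    sprintf("cellsize %.17g", g$cellsize),
    sprintf("NODATA_value %.17g", nodata))
  body <- apply(m, 1L, function(r) {
    r[!is.finite(r)] <- nodata
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Per-row pixel area in square kilometers
#'
#' Spherical cosine-of-latitude approximation:
#' `area = (cellsize * 111.195 km)^2 * cos(latitude of row center)`.
#'
#' @param g A `raster_grid` in geographic coordinates.
#' @param row Row index (1 = northernmost) or vector of indices.
#' @return Area(s) in km^2, strictly positive.
#' @export
pixel_area_km2 <- function(g, row) {
  lat <- grid_lats(g)[row]
  if (any(abs(lat) >= 90)) stop("row center latitude must satisfy |lat| < 90")
  (g$cellsize * KM_PER_DEG)^2 * cos(lat * pi / 180)
}

#' Total area of the 1-cells of a binary grid
#'
#' Sums latitude-aware pixel areas over cells equal to 1. NA cells contribute
#' nothing.
#'
#' @param g A `raster_grid` with values in `{0, 1, NA}`.
#' @return Area in km^2.
#' @export
binary_area_km2 <- function(g) {
  rows_area <- pixel_area_km2(g, seq_len(grid_nrow(g)))
  ones <- g$values == 1
  ones[is.na(ones)] <- FALSE
  sum(rows_area * rowSums(ones))
}

#' Resample a grid onto a template grid
#'
#' Continuous layers are interpolated bilinearly between source cell centers;
#' categorical layers take the value of the nearest source cell. Template
#' cells outside the source extent, or whose interpolation touches a nodata
#' cell, become NA.
#'
#' @param g Source `raster_grid`.
#' @param template `raster_grid` defining the output geometry.
#' @param method `"continuous"` (bilinear) or `"categorical"` (nearest).
#' @return A `raster_grid` on the template geometry.
#' @export
resample_to <- function(g, template, method = c("continuous", "categorical")) {
  method <- match.arg(method)
  if (same_grid(g, template)) {
    out <- g
    return(out)
  }
  # require overlap
  if (g$xmin >= grid_xmax(template) || grid_xmax(g) <= template$xmin ||
      grid_ymin(g) >= template$ymax || g$ymax <= grid_ymin(template)) {
    stop("source and template extents are disjoint for layer '", g$name, "'")
  }
  lon <- grid_lons(template); lat <- grid_lats(template)
  src_lon <- grid_lons(g); src_lat <- grid_lats(g)
  nr <- length(lat); nc <- length(lon)
  out <- matrix(NA_real_, nr, nc)
  if (method == "categorical") {
    ci <- round((lon - src_lon[1]) / g$cellsize) + 1
    ri <- round((src_lat[1] - lat) / g$cellsize) + 1
    okc <- ci >= 1 & ci <= grid_ncol(g)
    okr <- ri >= 1 & ri <= grid_nrow(g)
    out[okr, okc] <- g$values[ri[okr], ci[okc], drop = FALSE]
  } else {
    # fractional column/row positions of template centers among source centers
    fx <- (lon - src_lon[1]) / g$cellsize + 1
    fy <- (src_lat[1] - lat) / g$cellsize + 1
    x0 <- floor(fx); y0 <- floor(fy)
    # clamp interior so template centers on the source boundary still resolve
    x0 <- pmin(pmax(x0, 1), grid_ncol(g) - 1)
    y0 <- pmin(pmax(y0, 1), grid_nrow(g) - 1)
    wx <- fx - x0; wy <- fy - y0
    okc <- fx >= 1 - 1e-9 & fx <= grid_ncol(g) + 1e-9
    okr <- fy >= 1 - 1e-9 & fy <= grid_nrow(g) + 1e-9
    for (i in which(okr)) {
      r0 <- y0[i]; wyi <- wy[i]
      v00 <- g$values[r0, x0]; v10 <- g$values[r0 + 1, x0]
      v01 <- g$values[r0, x0 + 1]; v11 <- g$values[r0 + 1, x0 + 1]
      v <- (1 - wyi) * ((1 - wx) * v00 + wx * v01) +
        wyi * ((1 - wx) * v10 + wx * v11)
      v[!okc] <- NA_real_
      out[i, ] <- v
    }
  }
  raster_grid(out, xmin = template$xmin, ymax = template$ymax,
              cellsize = template$cellsize, crs = template$crs, name = g$name)
}

#' Construct a raster stack
#'
#' An ordered, named collection of `raster_grid` layers sharing one geometry.
#'
#' @param layers List of `raster_grid` objects with unique names.
#' @return An object of class `raster_stack` (a named list of layers).
#' @export
raster_stack <- function(layers) {
  if (!length(layers)) stop("empty stack")
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate layer names in stack")
  for (l in layers[-1]) {
    if (!same_grid(l, layers[[1]])) {
      stop("layer '", l$name, "' does not share the stack grid")
    }
  }
  names(layers) <- nms
  structure(layers, class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d layers (%s), %d x %d cells\n",
              length(x), paste(names(x), collapse = ", "),
              nrow(x[[1]]$values), ncol(x[[1]]$values)))
  invisible(x)
}

#' Align a set of layers onto a template grid
#'
#' Resamples every layer onto the template geometry: continuous layers
#' bilinearly, categorical layers by nearest neighbor. Layers already on the
#' template grid pass through unchanged, so alignment is idempotent.
#'
#' @param layers List of `raster_grid` objects.
#' @param template `raster_grid` defining the common geometry (typically the
#'   climate grid).
#' @param methods Character vector (`"continuous"`/`"categorical"`), recycled
#'   over layers.
#' @return A `raster_stack` on the template geometry.
#' @export
align_stack <- function(layers, template, methods = "continuous") {
  if (!length(layers)) stop("empty layer list")
  bad <- setdiff(unique(methods), c("continuous", "categorical"))
  if (length(bad)) stop("unknown resampling method: ", paste(bad, collapse = ", "))
  methods <- rep_len(methods, length(layers))
  raster_stack(Map(function(l, m) resample_to(l, template, m), layers, methods))
}

# clone a grid's geometry with new values
grid_like <- function(g, values, name = g$name) {
  if (is.null(dim(values))) dim(values) <- dim(g$values)
  if (!identical(dim(values), dim(g$values))) {
    stop("values shape does not match the template grid")
  }
  raster_grid(values, xmin = g$xmin, ymax = g$ymax, cellsize = g$cellsize,
              crs = g$crs, name = name)
}
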