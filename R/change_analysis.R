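# Present-vs-future change classification and area accounting: stable /
# gain / loss / unsuitable categories, km2 sums with latitude-aware pixel
# areas, percentages relative to the present suitable area, per-RCP
# averaging, and elevation-band summaries.

CHANGE_CODES <- c(unsuitable = 0, stable = 1, gain = 2, loss = 3)

#' Round half-up to a number of decimals
#'
#' Report tables round half-up (so 46.15 prints as 46.2), unlike base
#' `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Classify present-vs-future habitat change
#'
#' The category of a cell is determined solely by its (present, future)
#' bit pair: (1,1) stable, (0,1) gain, (1,0) loss, (0,0) unsuitable.
#' Nodata in either map propagates.
#'
#' @param present,future Aligned binary `raster_grid`s.
#' @return A `raster_grid` with integer codes 0 unsuitable, 1 stable,
#'   2 gain, 3 loss.
#' @export
classify_change <- function(present, future) {
  if (!same_grid(present, future)) stop("present/future grids do not match")
  p <- present$values; f <- future$values
  v <- ifelse(p == 1 & f == 1, CHANGE_CODES[["stable"]],
       ifelse(p == 0 & f == 1, CHANGE_CODES[["gain"]],
       ifelse(p == 1 & f == 0, CHANGE_CODES[["loss"]],
              CHANGE_CODES[["unsuitable"]])))
  grid_like(present, v, "change")
}

category_area <- function(change, code) {
  rows_area <- pixel_area_km2(change, seq_len(grid_nrow(change)))
  hits <- change$values == code
  hits[is.na(hits)] <- FALSE
  sum(rows_area * rowSums(hits))
}

#' Summarize change areas relative to the present suitable area
#'
#' Sums latitude-aware pixel areas per category and expresses each as a
#' percentage of the present suitable area (stable + loss), which is why
#' gain percentages can exceed 100.
#'
#' @param change Change `raster_grid` from [classify_change()].
#' @param scenario_id Label carried into the summary.
#' @return A `change_summary` list: `scenario_id`, `present_km2`, and per
#'   category `<cat>_km2` / `<cat>_pct` (raw doubles; use
#'   [format_change_summary()] for the one-decimal report view).
#' @export
summarize_areas <- function(change, scenario_id = "scenario") {
  stable <- category_area(change, CHANGE_CODES[["stable"]])
  gain <- category_area(change, CHANGE_CODES[["gain"]])
  loss <- category_area(change, CHANGE_CODES[["loss"]])
  unsuitable <- category_area(change, CHANGE_CODES[["unsuitable"]])
  present <- stable + loss
  if (present <= 0) stop("present suitable area is zero; percentages undefined")
  structure(list(scenario_id = scenario_id, present_km2 = present,
                 stable_km2 = stable, gain_km2 = gain, loss_km2 = loss,
                 unsuitable_km2 = unsuitable,
                 stable_pct = 100 * stable / present,
                 gain_pct = 100 * gain / present,
                 loss_pct = 100 * loss / present),
            class = "change_summary")
}

#' Build a change summary from category areas
#'
#' The Table-3-style accounting on printed numbers: the present suitable
#' area is `stable + loss` and every percentage is relative to it.
#'
#' @param stable_km2,gain_km2,loss_km2 Category areas in km^2.
#' @param present_km2 Present suitable area; defaults to
#'   `stable_km2 + loss_km2`.
#' @param scenario_id Label.
#' @return A `change_summary`.
#' @export
change_summary_from_areas <- function(stable_km2, gain_km2, loss_km2,
                                      present_km2 = stable_km2 + loss_km2,
                                      scenario_id = "scenario") {
  if (present_km2 <= 0) stop("present suitable area must be positive")
  structure(list(scenario_id = scenario_id, present_km2 = present_km2,
                 stable_km2 = stable_km2, gain_km2 = gain_km2,
                 loss_km2 = loss_km2, unsuitable_km2 = NA_real_,
                 stable_pct = 100 * stable_km2 / present_km2,
                 gain_pct = 100 * gain_km2 / present_km2,
                 loss_pct = 100 * loss_km2 / present_km2),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf(
    "%s: present %.0f km2 | stable %.0f (%.1f%%) gain %.0f (%.1f%%) loss %.0f (%.1f%%)\n",
    x$scenario_id, x$present_km2, x$stable_km2, x$stable_pct, x$gain_km2,
    x$gain_pct, x$loss_km2, x$loss_pct))
  invisible(x)
}

#' One-decimal report view of a change summary
#'
#' @param x A `change_summary`.
#' @return One-row data frame with areas and half-up-rounded percentages.
#' @export
format_change_summary <- function(x) {
  data.frame(scenario = x$scenario_id,
             present_km2 = round_half_up(x$present_km2, 0),
             stable_km2 = round_half_up(x$stable_km2, 0),
             stable_pct = round_half_up(x$stable_pct, 1),
             gain_km2 = round_half_up(x$gain_km2, 0),
             gain_pct = round_half_up(x$gain_pct, 1),
             loss_km2 = round_half_up(x$loss_km2, 0),
             loss_pct = round_half_up(x$loss_pct, 1))
}

#' Average change summaries across RCPs
#'
#' Arithmetic mean of category areas across scenarios sharing a horizon and
#' present map. Percentages are recomputed from the averaged areas; for
#' report parity with tables that average printed percentages, the means of
#' the member percentages are also emitted (`*_pct_mean`).
#'
#' @param summaries List of `change_summary` objects (e.g. one per RCP).
#' @param scenario_id Label of the averaged summary.
#' @return A `change_summary` with additional `stable_pct_mean`,
#'   `gain_pct_mean`, `loss_pct_mean` fields.
#' @export
average_scenarios <- function(summaries, scenario_id = "average") {
  if (!length(summaries)) stop("no summaries to average")
  get <- function(f) vapply(summaries, `[[`, numeric(1), f)
  out <- change_summary_from_areas(
    stable_km2 = mean(get("stable_km2")), gain_km2 = mean(get("gain_km2")),
    loss_km2 = mean(get("loss_km2")),
    present_km2 = mean(get("present_km2")), scenario_id = scenario_id)
  out$unsuitable_km2 <- mean(get("unsuitable_km2"))
  # report-parity averages: means of the one-decimal percentages as printed
  out$stable_pct_mean <- mean(round_half_up(get("stable_pct"), 1))
  out$gain_pct_mean <- mean(round_half_up(get("gain_pct"), 1))
  out$loss_pct_mean <- mean(round_half_up(get("loss_pct"), 1))
  out
}

#' Summarize change categories by elevation band
#'
#' Partitions the valid cells into fixed-width elevation bands and sums the
#' per-category areas in each; also reports the mean elevation of the cells
#' in each category.
#'
#' @param change Change `raster_grid`.
#' @param dem Aligned DEM `raster_grid` (meters).
#' @param band_width_m Band width in meters (> 0), default 200.
#' @return List with `bands` (data frame: `band_low_m`, `band_high_m`, and
#'   km^2 per category) and `mean_elevation` (named numeric per category).
#' @export
elevation_band_summary <- function(change, dem, band_width_m = 200) {
  if (band_width_m <= 0) stop("band width must be positive")
  if (!same_grid(change, dem)) stop("change/dem grids do not match")
  ok <- !is.na(change$values) & !is.na(dem$values)
  rows_area <- pixel_area_km2(change, seq_len(grid_nrow(change)))
  area_m <- matrix(rows_area, grid_nrow(change), grid_ncol(change))
  elev <- dem$values[ok]; cat <- change$values[ok]; ar <- area_m[ok]
  band <- floor(elev / band_width_m) * band_width_m
  levels_b <- sort(unique(band))
  bands <- data.frame(band_low_m = levels_b, band_high_m = levels_b + band_width_m)
  for (nm in names(CHANGE_CODES)) {
    code <- CHANGE_CODES[[nm]]
    bands[[paste0(nm, "_km2")]] <- vapply(levels_b, function(b) {
      sum(ar[band == b & cat == code])
    }, numeric(1))
  }
  mean_elev <- vapply(names(CHANGE_CODES), function(nm) {
    sel <- cat == CHANGE_CODES[[nm]]
    if (!any(sel)) NA_real_ else stats::weighted.mean(elev[sel], ar[sel])
  }, numeric(1))
  list(bands = bands, mean_elevation = mean_elev)
}
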