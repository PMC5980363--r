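# Binary maps, model-agreement ensembles, and GCM consensus.

#' Binarize a suitability surface
#'
#' Cells at or above the threshold become 1, below become 0; nodata is
#' preserved.
#'
#' @param surface Suitability `raster_grid` in `[0, 1]`.
#' @param threshold Threshold in `[0, 1]` (typically the frozen
#'   sensitivity = specificity threshold).
#' @return A binary `raster_grid`; the threshold is recorded in the
#'   `"threshold"` attribute.
#' @export
binarize <- function(surface, threshold) {
  if (!is.finite(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]")
  }
  out <- grid_like(surface, ifelse(surface$values >= threshold, 1, 0),
                   paste0(surface$name, "_bin"))
  attr(out, "threshold") <- threshold
  out
}

#' Sum binary maps into an agreement ensemble
#'
#' Cell-wise integer sum of aligned binary maps: the number of models (or
#' GCMs) agreeing that a cell is suitable. Nodata in any input propagates.
#'
#' @param maps List of at least 2 aligned binary `raster_grid`s.
#' @return A `raster_grid` of counts in `[0, length(maps)]`.
#' @export
agreement_sum <- function(maps) {
  if (length(maps) < 2) stop("need at least 2 maps")
  for (m in maps[-1]) {
    if (!same_grid(m, maps[[1]])) stop("maps do not share a grid")
  }
  acc <- maps[[1]]$values
  for (m in maps[-1]) acc <- acc + m$values
  grid_like(maps[[1]], acc, "agreement")
}

#' Consensus map from an agreement ensemble
#'
#' Cells where at least `k` models agree become 1.
#'
#' @param ensemble Agreement-count `raster_grid`.
#' @param k Minimum agreement count, in `[1, max attainable count]`.
#' @param max_count The number of maps that entered the ensemble; defaults
#'   to the maximum observed count.
#' @return A binary `raster_grid`.
#' @export
consensus <- function(ensemble, k, max_count = NULL) {
  if (is.null(max_count)) max_count <- max(ensemble$values, na.rm = TRUE)
  if (k < 1 || k > max_count) stop("k out of range [1, ", max_count, "]")
  grid_like(ensemble, ifelse(ensemble$values >= k, 1, 0),
            paste0("consensus_k", k))
}

#' Model-consensus map for one predictor stack
#'
#' Predicts all model surfaces on the stack, binarizes each at its frozen
#' threshold, sums the binaries, and applies the model-agreement cut.
#'
#' @param models List of `enm_model`s.
#' @param thresholds Numeric vector of frozen per-model thresholds (same
#'   order as `models`).
#' @param stack Predictor `raster_stack`.
#' @param k_models Minimum number of agreeing models (default 3 of 5).
#' @param scenario_id Label for the predicted surfaces.
#' @return List with `surfaces`, `binaries`, `count` (agreement grid), and
#'   `map` (binary consensus).
#' @export
model_consensus <- function(models, thresholds, stack, k_models = 3,
                            scenario_id = "present") {
  stopifnot(length(models) == length(thresholds))
  surfaces <- lapply(models, predict_surface, stack = stack,
                     scenario_id = scenario_id)
  binaries <- Map(binarize, surfaces, thresholds)
  count <- agreement_sum(binaries)
  list(surfaces = surfaces, binaries = binaries, count = count,
       map = consensus(count, k_models, max_count = length(models)))
}

#' Build a future scenario from GCM stacks
#'
#' For each GCM stack: predict the model surfaces, binarize at the frozen
#' present-day thresholds, and take the model consensus at `k_models`. The
#' per-GCM consensus maps are then summed and the final future map keeps
#' cells where at least `k_gcms` GCMs agree.
#'
#' @param models List of `enm_model`s.
#' @param thresholds Frozen present-day thresholds (one per model).
#' @param gcm_stacks Named list of future `raster_stack`s, one per GCM.
#' @param k_models Model-agreement cut (default 3).
#' @param k_gcms GCM-agreement cut (default 2).
#' @param scenario_id Scenario label.
#' @return List with `per_gcm` (binary model-consensus maps), `gcm_count`
#'   (agreement over GCMs), and `map` (final future binary map).
#' @export
build_scenario <- function(models, thresholds, gcm_stacks, k_models = 3,
                           k_gcms = 2, scenario_id = "future") {
  if (!length(gcm_stacks)) stop("no GCM stacks supplied")
  per_gcm <- lapply(seq_along(gcm_stacks), function(i) {
    id <- names(gcm_stacks)[i]
    if (is.null(id) || !nzchar(id)) id <- paste0("gcm", i)
    model_consensus(models, thresholds, gcm_stacks[[i]], k_models,
                    scenario_id = paste0(scenario_id, "_", id))$map
  })
  gcm_count <- agreement_sum(per_gcm)
  map <- consensus(gcm_count, k_gcms, max_count = length(per_gcm))
  map$name <- paste0("consensus_", scenario_id)
  list(per_gcm = per_gcm, gcm_count = gcm_count, map = map)
}
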