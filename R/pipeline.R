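# End-to-end orchestration: synthetic landscape -> occurrences -> background
# -> training table -> collinearity pruning -> five model fits -> evaluation
# -> present consensus -> GCM x RCP x horizon projections -> change
# accounting. Every stage is seeded from the single pipeline seed.

#' Pipeline configuration
#'
#' @param landscape A `landscape_config` (its seed drives the landscape).
#' @param species A `virtual_species` supplying the known truth.
#' @param n_occurrences Raw presence points to sample (default 976, a
#'   realistic multi-year field-survey effort).
#' @param n_background Background points inside the 95% MCP (default
#'   10,000).
#' @param split_fraction Training fraction of thinned presences (0.70).
#' @param mcp_retain MCP retain fraction (0.95).
#' @param prune_threshold Collinearity threshold (0.7, strict).
#' @param priority Predictor priority ranking; `NULL` uses
#'   [default_predictor_priority()] over the available layers.
#' @param families Model families to fit (default all five).
#' @param hyper Named list of per-family hyperparameter overrides, e.g.
#'   `list(brt = list(max_trees = 500))`.
#' @param k_models,k_gcms Consensus cuts (3 models, 2 GCMs).
#' @param rcps,horizons,n_gcms Scenario grid (default both RCPs, 2050 and
#'   2070, 4 pseudo-GCMs).
#' @param seed Master seed; all stage seeds derive from it.
#' @param outdir Output directory for artifacts, or `NULL` to skip writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(landscape = landscape_config(seed = seed),
                            species = virtual_species(),
                            n_occurrences = 976, n_background = 10000,
                            split_fraction = 0.70, mcp_retain = 0.95,
                            prune_threshold = 0.7, priority = NULL,
                            families = ENM_FAMILIES, hyper = list(),
                            k_models = 3, k_gcms = 2,
                            rcps = c("rcp45", "rcp85"),
                            horizons = c(2050, 2070), n_gcms = 4,
                            seed = 1L, outdir = NULL) {
  structure(list(landscape = landscape, species = species,
                 n_occurrences = n_occurrences,
                 n_background = n_background,
                 split_fraction = split_fraction, mcp_retain = mcp_retain,
                 prune_threshold = prune_threshold, priority = priority,
                 families = families, hyper = hyper, k_models = k_models,
                 k_gcms = k_gcms, rcps = rcps, horizons = horizons,
                 n_gcms = n_gcms, seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

# grid of 1 where every stack layer is valid, NA elsewhere
stack_validity <- function(stack) {
  ok <- Reduce(`&`, lapply(stack, function(g) !is.na(g$values)))
  grid_like(stack[[1]], ifelse(ok, 1, NA_real_), "valid")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full ensemble niche-modeling pipeline
#'
#' Executes thinning, 70/30 splitting, MCP background sampling, extraction,
#' collinearity pruning, the model fits, evaluation, the present-day
#' model-consensus map, all future GCM x RCP x horizon projections, and the
#' stable/gain/loss change accounting. When `config$outdir` is set, all
#' artifacts (CSV tables, ASCII grids, WKT polygon, JSON manifest) are
#' written there.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with every intermediate and final product:
#'   `landscape`, `occurrences`, `background`, `table`, `retained`,
#'   `models`, `evaluations`, `evaluation_table`, `thresholds`, `present`,
#'   `scenarios`, `summaries`, `averages`, `change_table`, `manifest`.
#' @export
run_pipeline <- function(config) {
  seed <- config$seed
  land <- run_stage("landscape", generate_landscape(config$landscape))
  stack <- land$predictors
  valid <- stack_validity(stack)

  occ_raw <- run_stage("occurrences", sample_occurrences(
    config$species, stack, config$n_occurrences, seed + 1L))
  thinned <- run_stage("thinning", thin_per_pixel(occ_raw, valid))
  occ <- run_stage("split", split_train_test(
    thinned, config$split_fraction, seed + 2L))

  bg <- run_stage("background", mcp_background(
    occ, valid, n_background = config$n_background,
    retain = config$mcp_retain, seed = seed + 3L))

  table <- run_stage("extraction", build_training_table(
    occ, bg$points, stack, seed = seed + 4L))

  priority <- config$priority
  if (is.null(priority)) priority <- default_predictor_priority(names(stack))
  retained <- run_stage("pruning", correlation_prune(
    table, priority, config$prune_threshold))
  table_p <- table[c(retained, "response", "role")]

  models <- list(); evals <- list()
  for (i in seq_along(config$families)) {
    fam <- config$families[i]
    spec <- model_spec(fam, hyper = config$hyper[[fam]] %||% list(),
                       seed = seed + 10L + i)
    models[[fam]] <- run_stage(paste0("fit_", fam),
                               fit_model(spec, table_p))
    evals[[fam]] <- run_stage(paste0("evaluate_", fam),
                              evaluate_model(models[[fam]], table_p))
  }
  thresholds <- vapply(evals, `[[`, numeric(1), "threshold")
  eval_table <- data.frame(
    family = names(evals),
    auc = vapply(evals, `[[`, numeric(1), "auc"),
    auc_class = vapply(evals, `[[`, character(1), "auc_class"),
    tss = vapply(evals, `[[`, numeric(1), "tss"),
    percent_correct = vapply(evals, `[[`, numeric(1), "percent_correct"),
    threshold = thresholds, row.names = NULL)

  present <- run_stage("present_consensus", model_consensus(
    models, thresholds, stack, config$k_models, "present"))

  scenarios <- list(); summaries <- list()
  scen_idx <- 0L
  for (h in config$horizons) for (rcp in config$rcps) {
    scen_idx <- scen_idx + 1L
    id <- sprintf("%s_%d", rcp, h)
    deltas <- gcm_deltas(rcp, h, config$n_gcms,
                         seed = seed + 1000L + scen_idx * 10L)
    gcm_stacks <- lapply(deltas, function(d) apply_scenario(stack, d))
    names(gcm_stacks) <- vapply(deltas, `[[`, character(1), "id")
    scen <- run_stage(paste0("scenario_", id), build_scenario(
      models, thresholds, gcm_stacks, config$k_models, config$k_gcms, id))
    change <- classify_change(present$map, scen$map)
    scen$change <- change
    scen$bands <- elevation_band_summary(change, land$dem)
    scenarios[[id]] <- scen
    summaries[[id]] <- summarize_areas(change, id)
  }

  averages <- lapply(config$horizons, function(h) {
    ids <- sprintf("%s_%d", config$rcps, h)
    average_scenarios(summaries[ids], sprintf("average_%d", h))
  })
  names(averages) <- sprintf("average_%d", config$horizons)

  change_table <- do.call(rbind, c(
    lapply(summaries, format_change_summary),
    lapply(averages, format_change_summary)))
  rownames(change_table) <- NULL

  manifest <- list(
    seed = seed,
    landscape = unclass(config$landscape),
    n_occurrences_raw = nrow(occ_raw),
    n_occurrences_thinned = nrow(thinned),
    n_train = sum(occ$role == "train"), n_test = sum(occ$role == "test"),
    n_background = config$n_background,
    mcp_wkt = bg$wkt,
    retained_predictors = as.character(retained),
    dropped_predictors = attr(retained, "dropped"),
    families = config$families,
    thresholds = as.list(thresholds),
    k_models = config$k_models, k_gcms = config$k_gcms,
    scenarios = names(scenarios),
    present_area_km2 = binary_area_km2(present$map))

  result <- list(landscape = land, occurrences = occ, background = bg,
                 table = table_p, retained = retained, models = models,
                 evaluations = evals, evaluation_table = eval_table,
                 thresholds = thresholds, present = present,
                 scenarios = scenarios, summaries = summaries,
                 averages = averages, change_table = change_table,
                 manifest = manifest)
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  utils::write.csv(result$occurrences, p("occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(result$background$points, p("background.csv"),
                   row.names = FALSE)
  writeLines(result$background$wkt, p("mcp.wkt"))
  utils::write.csv(result$evaluation_table, p("model_evaluation.csv"),
                   row.names = FALSE)
  utils::write.csv(result$change_table, p("change_summary.csv"),
                   row.names = FALSE)
  write_asc(result$landscape$dem, p("dem.asc"))
  write_asc(result$present$count, p("ensemble_count_present.asc"))
  write_asc(result$present$map, p("consensus_present.asc"))
  for (id in names(result$scenarios)) {
    scen <- result$scenarios[[id]]
    write_asc(scen$gcm_count, p(sprintf("ensemble_count_%s.asc", id)))
    write_asc(scen$map, p(sprintf("consensus_%s.asc", id)))
    write_asc(scen$change, p(sprintf("change_%s.asc", id)))
    utils::write.csv(scen$bands$bands, p(sprintf("elevation_bands_%s.csv", id)),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
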