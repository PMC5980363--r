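# Shared fixtures, built in code. The landscape cache avoids regenerating
# the same seeded landscape across test files.

.fixture_cache <- new.env(parent = emptyenv())

# small seeded landscape (default 60x60) with all derived layers
fixture_landscape <- function(n = 60, seed = 42) {
  key <- sprintf("land_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- landscape_config(nrow = n, ncol = n, seed = seed)
    .fixture_cache[[key]] <- list(config = cfg,
                                  land = generate_landscape(cfg))
  }
  .fixture_cache[[key]]
}

# small presence/background training table with known signal: presence
# scores drawn from shifted normals on x1, noise on the rest
fixture_table <- function(n1 = 150, n0 = 300, n_noise = 2, shift = 3,
                          seed = 1) {
  set.seed(seed)
  n <- n1 + n0
  tab <- data.frame(x1 = c(stats::rnorm(n1, shift / 2), stats::rnorm(n0, -shift / 2)))
  for (i in seq_len(n_noise)) {
    tab[[paste0("noise", i)]] <- stats::rnorm(n)
  }
  tab$response <- rep(c(1, 0), c(n1, n0))
  tab$role <- ifelse(stats::runif(n) < 0.7, "train", "test")
  tab
}

# plain grid helper: values matrix on a unit-degree-ish grid
fixture_grid <- function(values, cellsize = 0.1, xmin = 10, ymax = 45,
                         name = "layer") {
  raster_grid(as.matrix(values), xmin = xmin, ymax = ymax,
              cellsize = cellsize, name = name)
}

# fast hyperparameters for the slow families, used where the test subject
# is not the fitting accuracy itself
fast_hyper <- list(brt = list(max_trees = 150, cv_folds = 3),
                   rf = list(n_trees = 150),
                   maxent_like = list(cv_folds = 3, n_hinge_knots = 4))

fast_spec <- function(family, seed = 1) {
  model_spec(family, hyper = fast_hyper[[family]] %||% list(), seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
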