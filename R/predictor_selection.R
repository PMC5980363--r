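# Point x predictor training tables and greedy collinearity pruning.

#' Extract predictor values at points
#'
#' Cell-value lookup (no interpolation) of every stack layer at each point.
#' Rows touching any nodata cell, or falling outside the grid, are dropped
#' and counted in the `"n_dropped"` attribute.
#'
#' @param points Data frame with columns `lon`, `lat`; any other columns
#'   (e.g. `role`) are carried through.
#' @param stack A `raster_stack`.
#' @param response Optional response value recycled into a `response` column
#'   (1 = presence, 0 = background).
#' @return Data frame of predictor columns (stack layer names) plus carried
#'   columns.
#' @export
extract_values <- function(points, stack, response = NULL) {
  idx <- cell_index(stack[[1]], points$lon, points$lat)
  vals <- lapply(stack, function(g) {
    v <- rep(NA_real_, nrow(points))
    ok <- !is.na(idx$row)
    v[ok] <- g$values[cbind(idx$row[ok], idx$col[ok])]
    v
  })
  tab <- as.data.frame(vals)
  carried <- setdiff(names(points), c("lon", "lat"))
  for (cn in carried) tab[[cn]] <- points[[cn]]
  if (!is.null(response)) tab$response <- response
  ok <- stats::complete.cases(tab[names(stack)])
  if (!any(ok)) stop("all rows dropped: every point touches nodata")
  out <- tab[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Build the presence/background training table
#'
#' Stacks presence rows (`response = 1`, with train/test roles) on top of
#' background rows (`response = 0`). Background points all get role
#' `"train"` for threshold fitting plus a held-out background share for test
#' scoring, controlled by `background_test_fraction`.
#'
#' @param presence Data frame `lon`, `lat`, `role`.
#' @param background Data frame `lon`, `lat`.
#' @param stack Predictor `raster_stack`.
#' @param background_test_fraction Fraction of background rows labeled
#'   `"test"` (default 0.3, mirroring the presence split).
#' @param seed Seed for the background role assignment.
#' @return Training table data frame with predictor columns, `response`, and
#'   `role`.
#' @export
build_training_table <- function(presence, background, stack,
                                 background_test_fraction = 0.3, seed = 1L) {
  p <- extract_values(presence, stack, response = 1)
  bg <- background
  set.seed(seed)
  n_test <- floor(background_test_fraction * nrow(bg))
  bg$role <- "train"
  bg$role[sample.int(nrow(bg), n_test)] <- "test"
  b <- extract_values(bg, stack, response = 0)
  out <- rbind(p, b)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- attr(p, "n_dropped") + attr(b, "n_dropped")
  out
}

#' Prune collinear predictors
#'
#' Pearson correlations are computed on all rows; pairs with `|r|` strictly
#' above the threshold are visited in decreasing `|r|` order (ties broken by
#' the priority rank of the pair's best member, then of the other member)
#' and the lower-priority member of each still-retained pair is dropped.
#' Constant predictors (undefined r) are treated as uncorrelated, with a
#' warning.
#'
#' @param table Training table (or any data frame) containing the predictor
#'   columns.
#' @param priority Character vector ranking every predictor, most important
#'   first; the sole tie-breaker for which member of a pair is kept.
#' @param threshold Correlation threshold (default 0.7, strict `>`).
#' @return Character vector of retained predictor names, in priority order,
#'   with attributes `"dropped"` and `"cor_matrix"`.
#' @export
correlation_prune <- function(table, priority, threshold = 0.7) {
  preds <- intersect(priority, names(table))
  if (length(setdiff(priority, names(table)))) {
    stop("priority names absent from table: ",
         paste(setdiff(priority, names(table)), collapse = ", "))
  }
  extra <- setdiff(names(table), c(priority, "response", "role"))
  if (length(extra)) {
    stop("predictors missing from the priority ranking: ",
         paste(extra, collapse = ", "))
  }
  if (length(preds) < 2) stop("need at least 2 predictors")
  x <- as.matrix(table[preds])
  if (nrow(x) < 3) stop("need at least 3 rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant predictor(s) treated as uncorrelated: ",
            paste(preds[sds == 0], collapse = ", "))
  }
  cm <- suppressWarnings(stats::cor(x))
  cm[!is.finite(cm)] <- 0
  rank <- stats::setNames(seq_along(preds), preds)
  # strict inequality; the epsilon keeps correlations numerically equal to
  # the threshold (within double rounding) on the "kept" side
  pairs <- which(upper.tri(cm) & abs(cm) > threshold + 1e-10, arr.ind = TRUE)
  retained <- rep(TRUE, length(preds))
  names(retained) <- preds
  if (nrow(pairs)) {
    a <- preds[pairs[, 1]]; b <- preds[pairs[, 2]]
    r <- abs(cm[pairs])
    best <- pmin(rank[a], rank[b]); worst <- pmax(rank[a], rank[b])
    ord <- order(-r, best, worst)
    for (i in ord) {
      if (retained[a[i]] && retained[b[i]]) {
        drop_name <- if (rank[a[i]] < rank[b[i]]) b[i] else a[i]
        retained[drop_name] <- FALSE
      }
    }
  }
  out <- preds[retained[preds]]
  attr(out, "dropped") <- preds[!retained[preds]]
  attr(out, "cor_matrix") <- cm
  out
}

#' Default predictor priority ranking
#'
#' The order used when choosing between correlated predictors: the
#' bioclim variables most often implicated in mountain-ungulate habitat
#' (annual mean temperature first), then terrain ruggedness and the other
#' topographic and land-cover predictors. A reproducible stand-in for
#' expert, literature-based choice.
#'
#' @param available Optional character vector; when given, the ranking is
#'   filtered to these names and any unranked names are appended in their
#'   input order.
#' @return Character vector of predictor names, most important first.
#' @export
default_predictor_priority <- function(available = NULL) {
  base <- c("bio1", "bio2", "bio3", "bio4", "bio9", "bio15", "bio18",
            "tri", "aspect", "northness", "eastness", "slope",
            "vegetation", "sparse", "dist_escape", "dist_riparian")
  if (is.null(available)) return(base)
  c(intersect(base, available), setdiff(available, base))
}
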