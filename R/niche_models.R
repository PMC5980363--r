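# Five presence/background model families behind one fit/predict contract:
# stepwise logistic GLM, additive MARS (hand-rolled hinge selection + GCV
# pruning), boosted regression trees (xgboost), random forest, and a
# Maxent-style penalized logistic model (glmnet on linear + quadratic +
# hinge features). In the likelihood-based families, background rows are
# weighted so presence and background carry equal total weight.

ENM_FAMILIES <- c("glm_stepwise", "mars", "brt", "rf", "maxent_like")

#' Specify a niche model
#'
#' @param family One of `"glm_stepwise"`, `"mars"`, `"brt"`, `"rf"`,
#'   `"maxent_like"`.
#' @param hyper Named list of family hyperparameters, merged over defaults:
#'   brt: `learning_rate` (0.01), `depth` (3), `max_trees` (2000),
#'   `cv_folds` (10); rf: `n_trees` (500); mars: `max_terms` (21),
#'   `n_knots` (15), `penalty` (2); maxent_like: `n_hinge_knots` (8),
#'   `cv_folds` (5).
#' @param seed Integer seed used by every stochastic family.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family, hyper = list(), seed = 1L) {
  family <- match.arg(family, ENM_FAMILIES)
  defaults <- switch(family,
    glm_stepwise = list(),
    mars = list(max_terms = 21, n_knots = 15, penalty = 2),
    brt = list(learning_rate = 0.01, depth = 3, max_trees = 2000,
               cv_folds = 10, early_stopping = 50),
    rf = list(n_trees = 500),
    maxent_like = list(n_hinge_knots = 8, cv_folds = 5))
  defaults[names(hyper)] <- hyper
  structure(list(family = family, hyper = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

table_predictors <- function(table) {
  setdiff(names(table), c("response", "role"))
}

#' Fit a niche model
#'
#' Fits the requested family on the training rows (`role == "train"`) of a
#' presence/background table. Likelihood-based families (GLM, MARS, BRT,
#' Maxent-like) weight background rows by `n_presence / n_background` so
#' both classes carry equal total weight.
#'
#' @param spec A `model_spec`.
#' @param table Training table: predictor columns plus `response` (0/1) and
#'   `role` (`"train"`/`"test"`).
#' @return An `enm_model` with fields `family`, `fit`, `predictors`, `spec`.
#' @export
fit_model <- function(spec, table) {
  preds <- table_predictors(table)
  if (length(preds) < 2) stop("need at least 2 predictors")
  tr <- table[table$role == "train", , drop = FALSE]
  y <- tr$response
  if (length(unique(y)) < 2) stop("training table has a single class")
  x <- as.matrix(tr[preds])
  if (!all(is.finite(x))) stop("non-finite predictor values")
  w <- ifelse(y == 1, 1, sum(y == 1) / sum(y == 0))
  fit <- switch(spec$family,
    glm_stepwise = fit_glm_stepwise(x, y, w),
    mars = fit_mars(x, y, w, spec$hyper),
    brt = fit_brt(x, y, w, spec$hyper, spec$seed),
    rf = fit_rf(x, y, spec$hyper, spec$seed),
    maxent_like = fit_maxent_like(x, y, w, spec$hyper, spec$seed))
  structure(list(family = spec$family, fit = fit, predictors = preds,
                 spec = spec),
            class = "enm_model")
}

#' @export
print.enm_model <- function(x, ...) {
  cat(sprintf("enm_model: %s on %d predictors (%s)\n", x$family,
              length(x$predictors), paste(x$predictors, collapse = ", ")))
  invisible(x)
}

#' Predict suitability from a fitted niche model
#'
#' @param object An `enm_model`.
#' @param newdata Data frame containing every training predictor; extra
#'   columns are ignored. Rows with missing values yield `NA`.
#' @param ... Unused.
#' @return Numeric vector of suitabilities in `[0, 1]` (NA where input NA).
#' @export
predict.enm_model <- function(object, newdata, ...) {
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing)) {
    stop("newdata lacks training predictor(s): ",
         paste(missing, collapse = ", "))
  }
  x <- as.matrix(newdata[object$predictors])
  out <- rep(NA_real_, nrow(x))
  ok <- stats::complete.cases(x)
  if (any(ok)) {
    p <- switch(object$family,
      glm_stepwise = predict_glm_stepwise(object$fit, x[ok, , drop = FALSE]),
      mars = predict_mars(object$fit, x[ok, , drop = FALSE]),
      brt = predict_brt(object$fit, x[ok, , drop = FALSE]),
      rf = predict_rf(object$fit, x[ok, , drop = FALSE]),
      maxent_like = predict_maxent_like(object$fit, x[ok, , drop = FALSE]))
    out[ok] <- pmin(pmax(p, 0), 1)
  }
  out
}

# ---- stepwise logistic GLM ------------------------------------------------

fit_glm_stepwise <- function(x, y, w) {
  d <- data.frame(x)
  d$.y <- y
  .w <- w  # found through the formula environment when step() refits
  full <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = d, weights = .w))
  suppressWarnings(stats::step(full, direction = "both", trace = 0))
}

predict_glm_stepwise <- function(fit, x) {
  as.numeric(stats::predict(fit, newdata = data.frame(x), type = "response"))
}

# ---- MARS (additive): forward hinge selection + GCV pruning ---------------

mars_basis <- function(x, terms) {
  n <- nrow(x)
  B <- matrix(1, n, 1)
  for (i in seq_len(nrow(terms))) {
    v <- x[, terms$var[i]]
    h <- if (terms$dir[i] > 0) pmax(v - terms$knot[i], 0)
         else pmax(terms$knot[i] - v, 0)
    B <- cbind(B, h)
  }
  B
}

wrss <- function(B, y, w) {
  f <- stats::lm.wfit(B, y, w)
  sum(w * f$residuals^2)
}

fit_mars <- function(x, y, w, hyper) {
  vars <- colnames(x)
  cand <- do.call(rbind, lapply(vars, function(v) {
    ks <- unique(stats::quantile(x[, v],
                                 probs = seq(0.05, 0.95,
                                             length.out = hyper$n_knots)))
    data.frame(var = v, knot = as.numeric(ks))
  }))
  terms <- data.frame(var = character(0), knot = numeric(0),
                      dir = numeric(0))
  B <- matrix(1, nrow(x), 1)
  rss <- wrss(B, y, w)
  used <- rep(FALSE, nrow(cand))
  while (ncol(B) + 2 <= hyper$max_terms) {
    best <- NULL; best_rss <- rss
    for (ci in which(!used)) {
      v <- x[, cand$var[ci]]; k <- cand$knot[ci]
      Btry <- cbind(B, pmax(v - k, 0), pmax(k - v, 0))
      r <- wrss(Btry, y, w)
      if (r < best_rss - 1e-12) { best <- ci; best_rss <- r }
    }
    if (is.null(best) || best_rss > rss * (1 - 1e-6)) break
    v <- x[, cand$var[best]]; k <- cand$knot[best]
    B <- cbind(B, pmax(v - k, 0), pmax(k - v, 0))
    terms <- rbind(terms,
                   data.frame(var = cand$var[best], knot = k, dir = 1),
                   data.frame(var = cand$var[best], knot = k, dir = -1))
    used[best] <- TRUE
    rss <- best_rss
  }
  # backward pruning by generalized cross-validation
  n <- nrow(x)
  gcv <- function(B) {
    m <- ncol(B)
    cost <- m + hyper$penalty * (m - 1) / 2
    if (cost >= n) return(Inf)
    (wrss(B, y, w) / n) / (1 - cost / n)^2
  }
  keep <- seq_len(nrow(terms))
  best_keep <- keep; best_gcv <- gcv(mars_basis(x, terms))
  while (length(keep) > 0) {
    scores <- vapply(seq_along(keep), function(i) {
      gcv(mars_basis(x, terms[keep[-i], , drop = FALSE]))
    }, numeric(1))
    i <- which.min(scores)
    keep <- keep[-i]
    if (scores[i] < best_gcv) { best_gcv <- scores[i]; best_keep <- keep }
  }
  terms <- terms[best_keep, , drop = FALSE]
  B <- mars_basis(x, terms)
  gfit <- suppressWarnings(
    stats::glm.fit(B, y, weights = w, family = stats::binomial()))
  beta <- gfit$coefficients
  beta[is.na(beta)] <- 0
  list(terms = terms, beta = beta)
}

predict_mars <- function(fit, x) {
  B <- mars_basis(x, fit$terms)
  as.numeric(stats::plogis(B %*% fit$beta))
}

# ---- boosted regression trees (xgboost) -----------------------------------

fit_brt <- function(x, y, w, hyper, seed) {
  set.seed(seed)
  params <- list(objective = "binary:logistic", eta = hyper$learning_rate,
                 max_depth = hyper$depth, eval_metric = "logloss",
                 nthread = 1)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w)
  cv <- xgboost::xgb.cv(params = params, data = dtrain,
                        nrounds = hyper$max_trees, nfold = hyper$cv_folds,
                        early_stopping_rounds = hyper$early_stopping,
                        verbose = 0)
  n_trees <- cv$best_iteration
  if (is.null(n_trees) || !length(n_trees)) n_trees <- hyper$max_trees
  set.seed(seed)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = n_trees)
  list(booster = fit, n_trees = n_trees)
}

predict_brt <- function(fit, x) {
  as.numeric(stats::predict(fit$booster, xgboost::xgb.DMatrix(x)))
}

# ---- random forest --------------------------------------------------------

fit_rf <- function(x, y, hyper, seed) {
  set.seed(seed)
  yf <- factor(y, levels = c(0, 1))
  # balanced (down-sampled) trees: each tree sees equal presence and
  # background counts, the standard remedy for presence/background
  # imbalance in random-forest SDMs
  m <- min(table(yf))
  fit <- randomForest::randomForest(x = x, y = yf, ntree = hyper$n_trees,
                                    strata = yf, sampsize = c(m, m))
  # out-of-bag vote fractions: honest suitability scores for the training
  # rows, used when fitting the binarization threshold
  list(forest = fit, oob = as.numeric(fit$votes[, "1"]))
}

predict_rf <- function(fit, x) {
  as.numeric(stats::predict(fit$forest, newdata = x, type = "prob")[, "1"])
}

# ---- Maxent-style penalized logistic (maxnet equivalence) -----------------

maxent_features <- function(x, knots) {
  cols <- list()
  for (v in colnames(x)) {
    xv <- x[, v]
    cols[[paste0(v, "_lin")]] <- xv
    cols[[paste0(v, "_sq")]] <- xv^2
    for (k in seq_along(knots[[v]])) {
      t <- knots[[v]][k]
      cols[[paste0(v, "_hf", k)]] <- pmax(xv - t, 0)
      cols[[paste0(v, "_hr", k)]] <- pmax(t - xv, 0)
    }
  }
  do.call(cbind, cols)
}

fit_maxent_like <- function(x, y, w, hyper, seed) {
  knots <- lapply(colnames(x), function(v) {
    as.numeric(unique(stats::quantile(
      x[, v], probs = seq(0.1, 0.9, length.out = hyper$n_hinge_knots))))
  })
  names(knots) <- colnames(x)
  feats <- maxent_features(x, knots)
  set.seed(seed)
  cvfit <- glmnet::cv.glmnet(feats, y, family = "binomial", weights = w,
                             nfolds = hyper$cv_folds, alpha = 1,
                             standardize = TRUE)
  list(cvfit = cvfit, knots = knots)
}

predict_maxent_like <- function(fit, x) {
  feats <- maxent_features(x, fit$knots)
  as.numeric(stats::predict(fit$cvfit, newx = feats, s = "lambda.min",
                            type = "response"))
}

# ---- surfaces and importance ----------------------------------------------

#' Predict a suitability surface over a raster stack
#'
#' Applies the model's prediction contract cell-wise; nodata in any training
#' predictor propagates to the output.
#'
#' @param model An `enm_model`.
#' @param stack `raster_stack` containing every training predictor layer.
#' @param scenario_id Label recorded on the output grid name.
#' @return A `raster_grid` of suitabilities in `[0, 1]`, named
#'   `"<family>_<scenario_id>"`.
#' @export
predict_surface <- function(model, stack, scenario_id = "present") {
  missing <- setdiff(model$predictors, names(stack))
  if (length(missing)) {
    stop("stack lacks training predictor layer(s): ",
         paste(missing, collapse = ", "))
  }
  df <- as.data.frame(lapply(stack[model$predictors],
                             function(g) as.vector(g$values)))
  names(df) <- model$predictors
  p <- predict(model, df)
  g <- stack[[1]]
  grid_like(g, matrix(p, grid_nrow(g), grid_ncol(g)),
            paste0(model$family, "_", scenario_id))
}

#' Permutation variable importance
#'
#' Importance of a predictor is the mean drop in test-row AUC when that
#' predictor's column is permuted, averaged over `n_permutations` seeded
#' shuffles.
#'
#' @param model An `enm_model`.
#' @param table The training table the model was fitted on.
#' @param n_permutations Number of permutations per predictor (>= 1).
#' @param seed Integer seed.
#' @return Data frame `predictor`, `importance`, sorted by decreasing
#'   importance, with attribute `"baseline_auc"`.
#' @export
variable_importance <- function(model, table, n_permutations = 10, seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  te <- table[table$role == "test", , drop = FALSE]
  pres <- te$response == 1
  base_scores <- predict(model, te[model$predictors])
  base_auc <- roc_auc(base_scores[pres], base_scores[!pres])
  set.seed(seed)
  imp <- vapply(model$predictors, function(v) {
    drops <- vapply(seq_len(n_permutations), function(i) {
      perm <- te[model$predictors]
      perm[[v]] <- perm[[v]][sample.int(nrow(perm))]
      s <- predict(model, perm)
      base_auc - roc_auc(s[pres], s[!pres])
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- data.frame(predictor = model$predictors, importance = imp)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "baseline_auc") <- base_auc
  out
}
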