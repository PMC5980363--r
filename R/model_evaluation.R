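# Threshold-free (AUC) and threshold-dependent (sensitivity, specificity,
# TSS, %Co) accuracy measures, sensitivity = specificity thresholding, and
# calibration / deviance-residual diagnostics.

#' ROC AUC for presence vs background scores
#'
#' The probability that a randomly chosen presence outscores a randomly
#' chosen background point: the Mann-Whitney U statistic normalized by
#' `n1 * n2`, with ties counted 1/2.
#'
#' @param presence,background Numeric score vectors, both nonempty.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(presence, background) {
  n1 <- length(presence); n0 <- length(background)
  if (!n1 || !n0) stop("both score sets must be nonempty")
  r <- rank(c(presence, background))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold where sensitivity equals specificity
#'
#' Sweeps candidate thresholds -- the union of the observed scores and the
#' midpoints between consecutive distinct scores -- and returns the one
#' minimizing `|sensitivity - specificity|`, ties broken toward the smallest
#' threshold. Presences exactly at the threshold count as predicted present.
#'
#' @param presence,background Numeric score vectors.
#' @return The selected threshold.
#' @export
threshold_sens_eq_spec <- function(presence, background) {
  if (!length(presence) || !length(background)) {
    stop("both score sets must be nonempty")
  }
  s <- sort(unique(c(presence, background)))
  cand <- sort(unique(c(s, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2)))
  gap <- vapply(cand, function(t) {
    abs(mean(presence >= t) - mean(background < t))
  }, numeric(1))
  cand[which.min(gap)]  # which.min takes the first (smallest) on ties
}

#' Threshold-dependent classification metrics
#'
#' @param presence,background Numeric score vectors.
#' @param threshold Finite threshold; scores `>= threshold` are predicted
#'   present.
#' @return List with `sensitivity`, `specificity`, `tss`
#'   (`sens + spec - 1`), and `percent_correct` (0-100).
#' @export
classification_metrics <- function(presence, background, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  sens <- mean(presence >= threshold)
  spec <- mean(background < threshold)
  tp <- sum(presence >= threshold); tn <- sum(background < threshold)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1,
       percent_correct = 100 * (tp + tn) /
         (length(presence) + length(background)))
}

#' Swets accuracy class of an AUC
#'
#' `> 0.9` is `"high"`, 0.7-0.9 `"good"`, `< 0.7` `"low"`.
#'
#' @param auc AUC value.
#' @return Character label.
#' @export
swets_class <- function(auc) {
  if (auc > 0.9) "high" else if (auc >= 0.7) "good" else "low"
}

#' Calibration bins
#'
#' Equal-width probability bins over `[0, 1]` with the mean predicted score
#' and the observed presence fraction per bin. Bins with no observations
#' are dropped.
#'
#' @param scores Predicted suitabilities in `[0, 1]`.
#' @param labels 0/1 observed outcomes.
#' @param n_bins Number of bins, at least 2.
#' @return Data frame `bin`, `n`, `mean_predicted`, `observed_fraction`.
#' @export
calibration_bins <- function(scores, labels, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  bin <- pmin(pmax(ceiling(scores * n_bins), 1L), n_bins)
  agg <- lapply(split(seq_along(scores), bin), function(i) {
    data.frame(n = length(i), mean_predicted = mean(scores[i]),
               observed_fraction = mean(labels[i]))
  })
  out <- do.call(rbind, agg)
  out <- cbind(bin = as.integer(names(agg)), out)
  rownames(out) <- NULL
  out
}

#' Bernoulli deviance residuals
#'
#' `sign(y - p) * sqrt(-2 * (y log p + (1 - y) log(1 - p)))` with
#' probabilities clamped to `[1e-6, 1 - 1e-6]`.
#'
#' @param labels 0/1 observed outcomes.
#' @param probs Predicted probabilities.
#' @return Numeric vector of residuals.
#' @export
deviance_residuals <- function(labels, probs) {
  p <- pmin(pmax(probs, 1e-6), 1 - 1e-6)
  dev <- -2 * (labels * log(p) + (1 - labels) * log(1 - p))
  sign(labels - p) * sqrt(dev)
}

#' Evaluate a fitted niche model
#'
#' The binarization threshold is fitted on the training rows
#' (sensitivity = specificity) and then frozen; AUC, TSS, and %Co are
#' computed on the held-out test rows at that threshold. Calibration bins
#' and deviance residuals are computed on the test rows.
#'
#' @param model A fitted model with a `predict` method returning
#'   suitabilities.
#' @param table Training table with `response` and `role` columns.
#' @param n_bins Number of calibration bins.
#' @return An `enm_evaluation` list: `auc`, `auc_class`, `threshold`,
#'   `sensitivity`, `specificity`, `tss`, `percent_correct`, `calibration`,
#'   `deviance_residuals`.
#' @export
evaluate_model <- function(model, table, n_bins = 10) {
  pred_cols <- model$predictors
  scores <- predict(model, table[pred_cols])
  tr <- table$role == "train"; te <- table$role == "test"
  pres <- table$response == 1
  train_scores <- scores[tr]
  # random forests score their own training rows near 0/1; out-of-bag votes
  # are the honest training-row scores for threshold fitting
  if (!is.null(model$fit$oob) &&
      length(model$fit$oob) == sum(tr)) {
    train_scores <- model$fit$oob
  }
  thr <- threshold_sens_eq_spec(train_scores[pres[tr]],
                                train_scores[!pres[tr]])
  auc <- roc_auc(scores[te & pres], scores[te & !pres])
  cm <- classification_metrics(scores[te & pres], scores[te & !pres], thr)
  structure(list(
    family = model$family, auc = auc, auc_class = swets_class(auc),
    threshold = thr, sensitivity = cm$sensitivity,
    specificity = cm$specificity, tss = cm$tss,
    percent_correct = cm$percent_correct,
    calibration = calibration_bins(scores[te], table$response[te], n_bins),
    deviance_residuals = deviance_residuals(table$response[te], scores[te])),
    class = "enm_evaluation")
}

#' @export
print.enm_evaluation <- function(x, ...) {
  cat(sprintf(
    "%s: AUC %.3f (%s), TSS %.2f, %%Co %.1f at threshold %.3f\n",
    x$family, x$auc, x$auc_class, x$tss, x$percent_correct, x$threshold))
  invisible(x)
}
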