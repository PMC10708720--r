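#' Fit the coordination classifier to a study
#'
#' End-to-end fit: every raw epoch is preprocessed (band-pass 1-32 Hz,
#' average reference, baseline correction, downsampling to 64 Hz), reduced
#' to a binary coherence graph (Welch MSC thresholded at `threshold`),
#' embedded over anonymous walk patterns of `walk_length` steps, and the
#' pair dataset of absolute embedding differences is classified with
#' gradient-boosted trees under stratified k-fold cross-validation. The fit
#' stores pooled out-of-fold predictions, global and per-game metrics, the
#' per-game CI, the three metric-vs-CI regressions, and a final booster
#' trained on all observations for [predict.coord_fit()].
#'
#' @param study a `"coord_study"` from [generate_study()] (or a list with
#'   elements `epochs` and `choices` in the same layout).
#' @param walk_length anonymous-walk length in steps (default 5).
#' @param threshold coherence cutoff for graph construction.
#' @param cv a [cv_config()].
#' @param ... further arguments to [preprocess_epoch()].
#' @return Object of class `"coord_fit"`.
#' @examples
#' \dontrun{
#' study <- generate_study(study_config(seed = 11))
#' fit <- coordination_fit(study)
#' summary(fit)
#' }
#' @export
coordination_fit <- function(study, walk_length = 5, threshold = 0.5,
                             cv = cv_config(), ...) {
  embeddings <- embed_study(study, l = walk_length, threshold = threshold, ...)
  dataset <- build_pair_dataset(embeddings, study$choices)
  pred <- train_predict_cv(dataset, cv)
  conf <- confusion_counts(pred$pred, dataset$label)
  metrics <- class_metrics(conf)
  per_game <- per_game_metrics(pred$pred, dataset$label, dataset$game)
  ci <- ci_table(study$choices)
  per_game <- merge(ci, per_game, by = "game")
  regressions <- list(
    recall = metric_vs_ci_regression(per_game$recall, per_game$ci),
    precision = metric_vs_ci_regression(per_game$precision, per_game$ci),
    f1 = metric_vs_ci_regression(per_game$f1, per_game$ci))
  final <- fit_booster(feature_matrix(dataset), dataset$label, cv)
  structure(list(call = match.call(), walk_length = walk_length,
                 threshold = threshold, cv = cv,
                 embeddings = embeddings, dataset = dataset,
                 predictions = pred, confusion = conf, metrics = metrics,
                 per_game = per_game, regressions = regressions,
                 booster = final),
            class = "coord_fit")
}

#' @export
print.coord_fit <- function(x, ...) {
  cat("Coordination classifier fit\n")
  cat(sprintf("  %d pair observations (%d coordinated), walk length %d, threshold %.2f\n",
              nrow(x$dataset), sum(x$dataset$label), x$walk_length,
              x$threshold))
  cat(sprintf("  out-of-fold accuracy %.4f, positive-class F1 %.4f\n",
              x$metrics$accuracy, x$metrics$f1[["1"]]))
  invisible(x)
}

#' @export
summary.coord_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.coord_fit")
}

#' @export
print.summary.coord_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nConfusion (pooled out-of-fold):\n")
  print(f$confusion)
  cat("\nPer-class metrics:\n")
  tab <- rbind(precision = f$metrics$precision, recall = f$metrics$recall,
               f1 = f$metrics$f1)
  print(round(tab, 4))
  cat("\nPer-game metrics:\n")
  pg <- f$per_game
  pg$recall <- sprintf("%.3f (%d/%d)", pg$recall, pg$tp, pg$pos)
  pg$precision <- sprintf("%.3f (%d/%d)", pg$precision, pg$tp, pg$pred_pos)
  pg$f1 <- round(pg$f1, 3); pg$ci <- round(pg$ci, 3)
  print(pg[, c("game", "ci", "recall", "precision", "f1")], row.names = FALSE)
  cat("\nMetric ~ CI regressions:\n")
  for (nm in names(f$regressions)) {
    cat(sprintf("  %-10s ", nm)); print(f$regressions[[nm]])
  }
  invisible(x)
}

#' Predict coordination for new pair observations
#'
#' Applies the final booster (trained on all observations) to new pair
#' features.
#'
#' @param object a `"coord_fit"`.
#' @param newdata data.frame with the fit's `f*` feature columns, or a
#'   numeric feature matrix.
#' @param type `"prob"` for probabilities, `"label"` for 0/1 at threshold
#'   0.5.
#' @param ... unused.
#' @return Numeric (or integer) vector of predictions.
#' @export
predict.coord_fit <- function(object, newdata,
                              type = c("prob", "label"), ...) {
  type <- match.arg(type)
  x <- if (is.data.frame(newdata)) feature_matrix(newdata) else
    as.matrix(newdata)
  p <- predict(object$booster, xgboost::xgb.DMatrix(x))
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Plot per-game metrics against the coordination index
#'
#' Base-graphics scatter of per-game recall, precision and F1 against CI,
#' each with its least-squares line -- the difficulty sensitivity picture.
#'
#' @param x a `"coord_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.coord_fit <- function(x, ...) {
  pg <- x$per_game
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  for (nm in c("recall", "precision", "f1")) {
    graphics::plot(pg$ci, pg[[nm]], xlab = "coordination index (CI)",
                   ylab = nm, pch = 19, ...)
    r <- x$regressions[[nm]]
    graphics::abline(r$intercept, r$slope, lty = 2)
    graphics::mtext(sprintf("r = %.2f, p = %.2g", r$pearson_r, r$p_value),
                    cex = 0.8)
  }
  invisible(x)
}
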