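#' Cross-validation and booster configuration
#'
#' The gradient-boosted-tree hyperparameters are deliberately plain
#' defaults: 100 trees of depth 3 with the booster's stock learning rate
#' 0.3, binary logistic objective, single thread (for bit-reproducible
#' runs). All are exposed here.
#'
#' @param k number of stratified folds (>= 2); default 3.
#' @param nrounds number of boosting rounds (trees).
#' @param max_depth maximum tree depth.
#' @param eta learning rate.
#' @param seed RNG seed governing fold assignment and booster randomness.
#' @return Object of class `"cv_config"`.
#' @export
cv_config <- function(k = 3, nrounds = 100, max_depth = 3, eta = 0.3,
                      seed = 1L) {
  stopifnot(k >= 2, nrounds >= 1, max_depth >= 1, eta > 0)
  structure(list(k = as.integer(k), nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Partitions observations into `k` folds so that each class's members are
#' spread as evenly as possible: within every class, fold counts differ by
#' at most one. Deterministic given the seed.
#'
#' @param labels vector of class labels (both classes must be present).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold indices in `1:k`, same length as `labels`.
#' @examples
#' table(make_folds(rep(c(0, 1), c(387, 153)), k = 3, seed = 1),
#'       rep(c(0, 1), c(387, 153)))   # 129/51 per fold
#' @export
make_folds <- function(labels, k, seed = 1L) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k)
      stop("class ", cls, " has fewer members (", length(idx),
           ") than folds (", k, ")")
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Out-of-fold predictions from cross-validated boosted trees
#'
#' For each fold, fits an XGBoost binary classifier (identical
#' hyperparameters across folds) on the remaining folds and predicts the
#' held-out observations, so every observation receives exactly one
#' out-of-fold probability. Probabilities are thresholded at 0.5 into
#' labels.
#'
#' @param dataset pair table from [build_pair_dataset()] (or any data.frame
#'   with a `label` column and `f*` feature columns).
#' @param cv a [cv_config()].
#' @return `data.frame` with columns `fold`, `prob`, `pred`, one row per
#'   observation, in the dataset's row order.
#' @export
train_predict_cv <- function(dataset, cv = cv_config()) {
  labels <- dataset$label
  x <- feature_matrix(dataset)
  folds <- make_folds(labels, cv$k, cv$seed)
  prob <- numeric(length(labels))
  for (f in seq_len(cv$k)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2L)
      stop("training folds for fold ", f, " contain a single class")
    booster <- fit_booster(x[tr, , drop = FALSE], labels[tr], cv)
    prob[!tr] <- predict(booster,
                         xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
  }
  data.frame(fold = folds, prob = prob, pred = as.integer(prob >= 0.5))
}

fit_booster <- function(x, y, cv) {
  set.seed(cv$seed)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = cv$max_depth,
                  eta = cv$eta, nthread = 1, seed = cv$seed),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = cv$nrounds, verbose = 0)
}

#' Confusion counts
#'
#' @param pred predicted labels (0/1).
#' @param labels true labels (0/1), same length; class 1 is the positive
#'   (coordinated) class.
#' @return Object of class `"confusion"`: list with integer `tp`, `fp`,
#'   `fn`, `tn` summing to `length(labels)`.
#' @export
confusion_counts <- function(pred, labels) {
  if (length(pred) != length(labels))
    stop("`pred` and `labels` lengths differ")
  out <- list(tp = sum(pred == 1 & labels == 1),
              fp = sum(pred == 1 & labels == 0),
              fn = sum(pred == 0 & labels == 1),
              tn = sum(pred == 0 & labels == 0))
  structure(lapply(out, as.integer), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(predicted = c("0", "1"), truth = c("0", "1")))
  print(m)
  invisible(x)
}

#' Per-class precision, recall, F1 and accuracy
#'
#' Class 1 metrics are `tp/(tp+fp)` (precision) and `tp/(tp+fn)` (recall);
#' class 0 swaps the roles of `tn`/`tp`. F1 is the harmonic mean of a
#' class's precision and recall. A zero denominator yields `NA` (undefined),
#' never a silent 0.
#'
#' @param conf a `"confusion"` object (or list with `tp`, `fp`, `fn`, `tn`).
#' @return List with `accuracy` and named vectors `precision`, `recall`,
#'   `f1` over classes `"0"` and `"1"`.
#' @examples
#' m <- class_metrics(structure(list(tp = 120L, fp = 47L, fn = 33L,
#'                                   tn = 340L), class = "confusion"))
#' round(m$accuracy, 4)   # 0.8519
#' @export
class_metrics <- function(conf) {
  n <- conf$tp + conf$fp + conf$fn + conf$tn
  if (n == 0) stop("empty confusion counts")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- c("0" = safe_div(conf$tn, conf$tn + conf$fn),
            "1" = safe_div(conf$tp, conf$tp + conf$fp))
  rec  <- c("0" = safe_div(conf$tn, conf$tn + conf$fp),
            "1" = safe_div(conf$tp, conf$tp + conf$fn))
  f1 <- 2 * prec * rec / (prec + rec)
  list(accuracy = (conf$tp + conf$tn) / n,
       precision = prec, recall = rec, f1 = f1)
}

#' Positive-class metrics per game
#'
#' Pools the out-of-fold predictions and computes, for each game, the
#' positive-class recall, precision and F1 along with the raw count
#' fractions they come from (`tp/pos`, `tp/pred_pos`). Games with no
#' positive instance get `NA` recall; games with no positive prediction get
#' `NA` precision.
#'
#' @param pred predicted labels (0/1), pooled out-of-fold.
#' @param labels true labels (0/1).
#' @param game_ids game identifier per observation.
#' @return `data.frame` with one row per game: `game`, `tp`, `pos`,
#'   `pred_pos`, `recall`, `precision`, `f1`.
#' @export
per_game_metrics <- function(pred, labels, game_ids) {
  stopifnot(length(pred) == length(labels), length(labels) == length(game_ids))
  games <- sort(unique(game_ids))
  out <- data.frame(game = games, tp = NA_integer_, pos = NA_integer_,
                    pred_pos = NA_integer_, recall = NA_real_,
                    precision = NA_real_, f1 = NA_real_)
  for (r in seq_along(games)) {
    sel <- game_ids == games[r]
    cm <- confusion_counts(pred[sel], labels[sel])
    met <- class_metrics(cm)
    out$tp[r] <- cm$tp
    out$pos[r] <- cm$tp + cm$fn
    out$pred_pos[r] <- cm$tp + cm$fp
    out$recall[r] <- met$recall[["1"]]
    out$precision[r] <- met$precision[["1"]]
    out$f1[r] <- met$f1[["1"]]
  }
  out
}

#' Area under the ROC curve of out-of-fold probabilities
#'
#' @param prob predicted probabilities.
#' @param labels true 0/1 labels.
#' @return AUC in \[0, 1\] (via \pkg{pROC}).
#' @export
oof_auc <- function(prob, labels) {
  as.numeric(pROC::auc(pROC::roc(labels, prob, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}
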