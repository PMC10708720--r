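test_that("stratified folds split each class evenly", {
  labels <- rep(c(1, 0), c(153, 387))
  folds <- make_folds(labels, k = 3, seed = 1)
  tab <- table(folds, labels)
  expect_equal(unname(tab[, "1"]), rep(51L, 3))
  expect_equal(unname(tab[, "0"]), rep(129L, 3))
  expect_identical(make_folds(labels, k = 3, seed = 1), folds)
  expect_false(identical(make_folds(labels, k = 3, seed = 2), folds))
  expect_error(make_folds(c(0, 0, 0, 1, 1), k = 3), "fewer members")
  # leave-one-out on a balanced toy: singleton folds
  expect_equal(sort(unique(make_folds(rep(0:1, 3), k = 3, seed = 1))), 1:3)
})

test_that("cross-validation is exact on separable data and reproducible", {
  set.seed(10)
  n <- 120
  y <- rep(0:1, each = n / 2)
  # f1 takes exactly two values so no held-out point can fall outside the
  # training range of its class (tree splits extrapolate poorly there)
  ds <- data.frame(label = y, f1 = as.numeric(y), f2 = rnorm(n))
  cv <- cv_config(k = 3, nrounds = 30, seed = 4)
  pred <- train_predict_cv(ds, cv)
  expect_equal(mean(pred$pred == y), 1)
  expect_equal(nrow(pred), n)
  expect_true(all(table(pred$fold) == n / 3))
  expect_identical(train_predict_cv(ds, cv), pred)
})

test_that("label-independent features give chance-level AUC", {
  aucs <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 150
    ds <- data.frame(label = rbinom(n, 1, 0.3),
                     matrix(runif(n * 8), n,
                            dimnames = list(NULL, paste0("f", 1:8))))
    pred <- train_predict_cv(ds, cv_config(k = 3, nrounds = 30, seed = s))
    oof_auc(pred$prob, ds$label)
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("confusion counts tally and transform correctly", {
  pred <- c(1, 1, 0, 0, 1, 0)
  truth <- c(1, 0, 1, 0, 1, 0)
  cm <- confusion_counts(pred, truth)
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 1L, fn = 1L, tn = 2L))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 6L)

  perfect <- confusion_counts(truth, truth)
  expect_equal(perfect$fp + perfect$fn, 0L)

  inv <- confusion_counts(1 - pred, truth)
  expect_equal(inv$tp, cm$fn); expect_equal(inv$fn, cm$tp)
  expect_equal(inv$fp, cm$tn); expect_equal(inv$tn, cm$fp)
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "lengths differ")
})

test_that("per-class metrics handle perfect, reference and degenerate counts", {
  cm <- structure(list(tp = 120L, fp = 47L, fn = 33L, tn = 340L),
                  class = "confusion")
  m <- class_metrics(cm)
  expect_equal(m$accuracy, 460 / 540)
  expect_equal(unname(m$precision), c(340 / 373, 120 / 167))
  expect_equal(unname(m$recall), c(340 / 387, 120 / 153))
  expect_equal(unname(m$f1[["1"]]), 240 / 320)

  p <- class_metrics(structure(list(tp = 5L, fp = 0L, fn = 0L, tn = 7L),
                               class = "confusion"))
  expect_true(all(unlist(p[c("precision", "recall", "f1")]) == 1))

  nopos <- class_metrics(structure(list(tp = 0L, fp = 0L, fn = 0L, tn = 9L),
                                   class = "confusion"))
  expect_true(is.na(nopos$precision[["1"]]))   # undefined, not zero
  expect_true(is.na(nopos$recall[["1"]]))
  expect_error(class_metrics(structure(list(tp = 0L, fp = 0L, fn = 0L,
                                            tn = 0L), class = "confusion")),
               "empty")
})

test_that("per-game metrics conserve counts and match the global pool", {
  set.seed(11)
  n <- 90
  games <- rep(1:3, each = 30)
  truth <- rbinom(n, 1, 0.4)
  pred <- ifelse(runif(n) < 0.8, truth, 1 - truth)
  pg <- per_game_metrics(pred, truth, games)
  expect_equal(nrow(pg), 3)
  glob <- confusion_counts(pred, truth)
  expect_equal(sum(pg$tp), glob$tp)
  expect_equal(sum(pg$pos), glob$tp + glob$fn)

  single <- per_game_metrics(pred, truth, rep(1, n))
  m <- class_metrics(glob)
  expect_equal(single$recall, unname(m$recall[["1"]]))
  expect_equal(single$precision, unname(m$precision[["1"]]))

  # a game with no positives: undefined recall flagged as NA
  pg2 <- per_game_metrics(c(0, 0, 1, 0), c(0, 0, 1, 1), c(1, 1, 2, 2))
  expect_true(is.na(pg2$recall[1]))
  expect_equal(pg2$recall[2], 0.5)
})
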