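#' Published per-game results of the reference coordination study
#'
#' Worked-example numbers from the original 10-player, 12-game tacit
#' coordination EEG experiment that this package's pipeline models: each
#' game's coordination index together with the classifier's positive-class
#' counts (true positives `tp`, actual positives `pos`, predicted positives
#' `pred_pos`) and the published recall/precision/F1. These serve as fixed
#' inputs for validating the metric arithmetic and the difficulty
#' sensitivity analysis; they are not recomputable here because the raw
#' recordings are available only on request from their custodians.
#'
#' @return `data.frame` with one row per game: `game`, `ci`, `tp`, `pos`,
#'   `pred_pos`, `recall`, `precision`, `f1`.
#' @seealso [reference_confusion()] for the pooled counts.
#' @export
reference_game_table <- function() {
  data.frame(
    game = 1:12,
    ci = c(0.311, 0.266, 0.266, 0.178, 0.356, 0.222,
           0.444, 0.289, 0.178, 0.289, 0.200, 0.400),
    tp = c(12L, 7L, 8L, 4L, 15L, 6L, 20L, 11L, 5L, 10L, 5L, 17L),
    pos = c(14L, 12L, 12L, 8L, 16L, 10L, 20L, 13L, 8L, 13L, 9L, 18L),
    pred_pos = c(17L, 9L, 10L, 4L, 22L, 7L, 33L, 15L, 5L, 13L, 5L, 27L),
    recall = c(0.857, 0.583, 0.667, 0.500, 0.937, 0.600,
               1.000, 0.846, 0.625, 0.769, 0.556, 0.944),
    precision = c(0.706, 0.778, 0.800, 1.000, 0.682, 0.857,
                  0.606, 0.733, 1.000, 0.769, 1.000, 0.623),
    f1 = c(0.774, 0.774, 0.727, 0.667, 0.789, 0.706,
           0.755, 0.786, 0.769, 0.769, 0.714, 0.756))
}

#' Pooled confusion counts of the reference study
#'
#' The full-model confusion of the reference experiment, reconstructed from
#' its published fractions: 540 pair observations of which 153 were
#' coordinated, 120/153 recalled and 120/167 of positive predictions
#' correct, giving tp = 120, fp = 47, fn = 33, tn = 340.
#'
#' @return A `"confusion"` object (see [confusion_counts()]).
#' @examples
#' class_metrics(reference_confusion())$accuracy   # 460/540
#' @export
reference_confusion <- function() {
  structure(list(tp = 120L, fp = 47L, fn = 33L, tn = 340L),
            class = "confusion")
}
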