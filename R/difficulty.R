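#' Coordination index of one game
#'
#' `CI = sum_j m_j (m_j - 1) / (N (N - 1))`, where `m_j` counts the players
#' who chose option j and `N` is the number of players. This is the
#' probability that two randomly drawn distinct players picked the same
#' option: 1 means unanimity (easiest coordination), 0 means no two players
#' agreed (hardest).
#'
#' @param m integer vector of per-option counts (a game's tally).
#' @param n_players total player count; defaults to `sum(m)`.
#' @return Scalar in \[0, 1\].
#' @examples
#' compute_ci(c(3, 3, 2, 2))   # 16/90
#' compute_ci(c(5, 5))         # 40/90
#' @export
compute_ci <- function(m, n_players = sum(m)) {
  if (n_players < 2) stop("CI needs at least 2 players")
  if (any(m < 0) || sum(m) != n_players)
    stop("tally must be non-negative and sum to n_players")
  sum(m * (m - 1)) / (n_players * (n_players - 1))
}

#' Per-game coordination indices
#'
#' @param choices choice matrix (players x games) from [sample_choices()].
#' @return `data.frame` with columns `game` and `ci`.
#' @export
ci_table <- function(choices) {
  n_games <- ncol(choices)
  ci <- vapply(seq_len(n_games), function(g)
    compute_ci(choice_tally(choices, g), nrow(choices)), 0)
  data.frame(game = seq_len(n_games), ci = ci)
}

#' Simple regression of a per-game metric on CI
#'
#' Ordinary least squares of the metric on the coordination index, with the
#' Pearson correlation and the two-sided t-test p-value for a zero slope
#' (n - 2 degrees of freedom; identical to the correlation test in simple
#' regression).
#'
#' @param metric per-game metric values (no missing entries).
#' @param ci per-game coordination indices, same length (>= 3).
#' @return Object of class `"ci_regression"`: list with `slope`,
#'   `intercept`, `pearson_r`, `p_value`, `n`.
#' @export
metric_vs_ci_regression <- function(metric, ci) {
  if (length(metric) != length(ci)) stop("lengths differ")
  keep <- !(is.na(metric) | is.na(ci))
  metric <- metric[keep]; ci <- ci[keep]
  if (length(ci) < 3) stop("need at least 3 complete (metric, CI) pairs")
  if (var(ci) == 0) stop("CI has zero variance; regression undefined")
  fit <- lm(metric ~ ci)
  s <- summary(fit)$coefficients
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson_r = cor(ci, metric),
                 p_value = unname(s["ci", "Pr(>|t|)"]),
                 n = length(ci)),
            class = "ci_regression")
}

#' @export
print.ci_regression <- function(x, ...) {
  cat(sprintf("metric ~ CI (n = %d): slope %.4f, intercept %.4f, r = %.4f, p = %.3g\n",
              x$n, x$slope, x$intercept, x$pearson_r, x$p_value))
  invisible(x)
}

#' Relative spread of per-game F1 scores
#'
#' `(max - min) / max * 100`, in percent: how much of its best value the F1
#' score loses across games.
#'
#' @param f1 per-game F1 values (>= 2 defined values, max > 0).
#' @return Percentage spread.
#' @export
f1_spread <- function(f1) {
  f1 <- f1[!is.na(f1)]
  if (length(f1) < 2) stop("need at least 2 defined F1 values")
  if (max(f1) == 0) stop("all F1 values are zero; spread undefined")
  (max(f1) - min(f1)) / max(f1) * 100
}
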