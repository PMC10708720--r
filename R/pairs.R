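#' All unordered player pairs
#'
#' @param n_players number of players (>= 2).
#' @return Two-column integer matrix (`i`, `j`) with `i < j`, one row per
#'   pair, sorted; `choose(n, 2)` rows (45 for 10 players).
#' @export
enumerate_pairs <- function(n_players) {
  if (n_players < 2) stop("need at least 2 players")
  idx <- which(upper.tri(diag(n_players)), arr.ind = TRUE)
  m <- cbind(i = idx[, "row"], j = idx[, "col"])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Pair feature: elementwise absolute embedding difference
#'
#' @param e_i,e_j embedding vectors of equal dimension.
#' @return `abs(e_i - e_j)`; symmetric in its arguments, non-negative.
#' @export
pair_feature <- function(e_i, e_j) {
  if (length(e_i) != length(e_j))
    stop("embedding dimensions differ: ", length(e_i), " vs ", length(e_j))
  abs(e_i - e_j)
}

#' Coordination label for one pair in one game
#'
#' @param choice_i,choice_j the two players' options in the same game.
#' @return `1L` if they coordinated (identical options), else `0L`.
#' @export
label_pair <- function(choice_i, choice_j) {
  as.integer(choice_i == choice_j)
}

#' Build the pair observation table
#'
#' One observation per (unordered player pair, game): the elementwise
#' absolute difference between the two players' embedding vectors, labeled 1
#' if they chose the same option and 0 otherwise. With 10 players and 12
#' games this is 45 x 12 = 540 observations.
#'
#' @param embeddings matrix from [embed_study()]: rows `p<p>_g<g>`, one
#'   column per walk pattern.
#' @param choices choice matrix (players x games) from [sample_choices()].
#' @return `data.frame` with columns `pair_i`, `pair_j`, `game`, `label`,
#'   then one feature column per pattern (original pattern strings kept in
#'   `attr(, "patterns")`).
#' @examples
#' \dontrun{
#' ds <- build_pair_dataset(embed_study(study), study$choices)
#' nrow(ds)  # choose(n_players, 2) * n_games
#' }
#' @export
build_pair_dataset <- function(embeddings, choices) {
  n_players <- nrow(choices); n_games <- ncol(choices)
  pairs <- enumerate_pairs(n_players)
  pats <- colnames(embeddings)
  rows <- vector("list", nrow(pairs) * n_games)
  k <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    for (g in seq_len(n_games)) {
      ri <- sprintf("p%d_g%d", i, g); rj <- sprintf("p%d_g%d", j, g)
      for (rr in c(ri, rj)) if (!rr %in% rownames(embeddings))
        stop("missing embedding for (player, game) = ", rr)
      k <- k + 1L
      rows[[k]] <- c(i, j, g, label_pair(choices[i, g], choices[j, g]),
                     pair_feature(embeddings[ri, ], embeddings[rj, ]))
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("pair_i", "pair_j", "game", "label",
                  paste0("f", seq_along(pats)))
  out$pair_i <- as.integer(out$pair_i); out$pair_j <- as.integer(out$pair_j)
  out$game <- as.integer(out$game); out$label <- as.integer(out$label)
  attr(out, "patterns") <- pats
  out
}

#' Extract the feature columns of a pair dataset as a matrix
#'
#' @param dataset a data.frame from [build_pair_dataset()] (any data.frame
#'   with `f<k>` feature columns).
#' @return Numeric matrix of the `f*` columns, rows in dataset order.
#' @export
feature_matrix <- function(dataset) {
  as.matrix(dataset[, grep("^f[0-9]+$", names(dataset)), drop = FALSE])
}
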