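#' Anonymize a walk
#'
#' Replaces each node in a walk by the order of its first appearance, so
#' (F3, Cz, F3, Pz, Cz, O1) becomes (1, 2, 1, 3, 2, 4). Two walks are the
#' same "anonymous walk" iff they visit nodes in the same revisit pattern,
#' regardless of which nodes they are.
#'
#' @param nodes vector of node identifiers; consecutive entries must differ
#'   (walks on a simple graph have no self-loops).
#' @return Integer vector of the same length, starting at 1.
#' @examples
#' anonymize_walk(c("F3", "Cz", "F3", "Pz", "Cz", "O1"))
#' @export
anonymize_walk <- function(nodes) {
  if (length(nodes) >= 2L &&
      any(nodes[-1] == nodes[-length(nodes)]))
    stop("walk revisits a node in consecutive steps (self-loop)")
  match(nodes, unique(nodes))
}

#' Enumerate all anonymous walk patterns of a given length
#'
#' A pattern of `l` steps is an integer sequence of length `l + 1` starting
#' at 1, in which each entry exceeds the running maximum by at most one and
#' consecutive entries differ. The patterns are returned in lexicographic
#' order, which is the canonical index of the embedding vector everywhere in
#' this package. Their count equals the Bell number B(l): 1, 2, 5, 15, 52,
#' 203 for l = 1..6, so walk length 5 yields 52-dimensional embeddings.
#'
#' @param l number of steps (>= 1).
#' @return List of integer vectors, lexicographically sorted.
#' @examples
#' enumerate_walk_patterns(3)   # 5 patterns
#' @export
enumerate_walk_patterns <- function(l) {
  if (l < 1) stop("walk length `l` must be >= 1")
  acc <- list()
  grow <- function(prefix, mx) {
    if (length(prefix) == l + 1L) {
      acc[[length(acc) + 1L]] <<- prefix
      return(invisible())
    }
    for (nxt in seq_len(mx + 1L)) {
      if (nxt == prefix[length(prefix)]) next
      grow(c(prefix, nxt), max(mx, nxt))
    }
  }
  grow(1L, 1L)
  acc  # generated in lexicographic order by construction
}

#' Pattern label strings
#'
#' @param patterns list from [enumerate_walk_patterns()].
#' @return Character vector such as `"1-2-1-3"`; used as embedding names and
#'   CSV headers.
#' @export
pattern_labels <- function(patterns) {
  vapply(patterns, paste, "", collapse = "-")
}

#' Anonymous-walk embedding of a coherence graph
#'
#' Represents a graph as the probability distribution over anonymous walk
#' patterns of `l` steps under the uniform random-walk law: the start node
#' is uniform over non-isolated nodes and each step moves to a uniformly
#' chosen neighbor. `mode = "exact"` computes the distribution by dynamic
#' programming over all walks (exact to machine precision; the 16-node,
#' 5-step walk space is ~1.2e7 paths and is traversed in compiled code);
#' `mode = "sampled"` estimates it from `n_samples` simulated walks.
#'
#' An edgeless graph admits no walks and embeds to the all-zero vector (with
#' a warning in sampled mode); any graph with at least one edge yields a
#' probability vector summing to 1. The embedding is invariant under node
#' relabeling (graph isomorphism).
#'
#' @param graph a `"coherence_graph"` adjacency matrix (or any symmetric
#'   0/1 matrix with zero diagonal).
#' @param l walk length in steps; default 5 (52 patterns).
#' @param mode `"exact"` or `"sampled"`.
#' @param n_samples number of walks in sampled mode.
#' @param seed optional seed for sampled mode.
#' @return Named numeric vector over the canonical pattern order.
#' @examples
#' k3 <- matrix(1, 3, 3) - diag(3)
#' walk_embedding(k3, l = 2)   # (1/2, 1/2) over "1-2-1", "1-2-3"
#' @export
walk_embedding <- function(graph, l = 5, mode = c("exact", "sampled"),
                           n_samples = 10000, seed = NULL) {
  mode <- match.arg(mode)
  adj <- unclass(graph)
  stopifnot(nrow(adj) == ncol(adj))
  patterns <- enumerate_walk_patterns(l)
  labs <- pattern_labels(patterns)
  if (sum(adj) == 0) {
    if (mode == "sampled") warning("edgeless graph: no walks; zero embedding")
    return(setNames(numeric(length(patterns)), labs))
  }
  if (mode == "exact") {
    v <- exact_walk_probs_cpp(adj, as.integer(l), patterns)
  } else {
    if (!is.null(seed)) set.seed(seed)
    v <- sampled_walk_probs_cpp(adj, as.integer(l), as.integer(n_samples),
                                patterns)
  }
  setNames(v, labs)
}

#' Embed every epoch of a study
#'
#' Convenience wrapper running preprocess -> coherence -> threshold ->
#' embedding over all (player, game) epochs.
#'
#' @param study a `"coord_study"` from [generate_study()], or a nested list
#'   `epochs[[player]][[game]]` of raw [eeg_epoch()] objects.
#' @param l walk length in steps.
#' @param threshold coherence cutoff for [threshold_graph()].
#' @param ... further arguments to [preprocess_epoch()].
#' @return Numeric matrix, one row per epoch (rownames `p<p>_g<g>`), one
#'   column per canonical pattern.
#' @export
embed_study <- function(study, l = 5, threshold = 0.5, ...) {
  epochs <- if (inherits(study, "coord_study")) study$epochs else study
  n_p <- length(epochs); n_g <- length(epochs[[1]])
  dim_l <- length(enumerate_walk_patterns(l))
  emb <- matrix(0, n_p * n_g, dim_l)
  rn <- character(n_p * n_g)
  k <- 0L
  for (p in seq_len(n_p)) {
    for (g in seq_len(n_g)) {
      k <- k + 1L
      pre <- preprocess_epoch(epochs[[p]][[g]], ...)
      gph <- threshold_graph(pairwise_coherence(pre), threshold)
      e <- walk_embedding(gph, l = l)
      emb[k, ] <- e
      if (k == 1L) colnames(emb) <- names(e)
      rn[k] <- sprintf("p%d_g%d", p, g)
    }
  }
  rownames(emb) <- rn
  emb
}

#' Choose the walk length by downstream cross-validated F1
#'
#' Grid search over candidate walk lengths: for each candidate the study is
#' embedded, the pair dataset built, and the classifier evaluated under
#' stratified k-fold cross-validation; the candidate with the highest
#' pooled out-of-fold positive-class F1 wins, ties going to the smaller
#' length. Deterministic given the cross-validation seed.
#'
#' @param study a `"coord_study"`.
#' @param lengths integer vector of candidate walk lengths.
#' @param cv a [cv_config()].
#' @return List with `length` (the chosen value) and `f1` (named vector of
#'   the candidates' cross-validated F1 scores).
#' @export
tune_walk_length <- function(study, lengths, cv = cv_config()) {
  if (length(lengths) == 0) stop("no candidate walk lengths supplied")
  lengths <- sort(unique(as.integer(lengths)))
  f1s <- setNames(numeric(length(lengths)), lengths)
  for (i in seq_along(lengths)) {
    emb <- embed_study(study, l = lengths[i])
    ds <- build_pair_dataset(emb, study$choices)
    pred <- train_predict_cv(ds, cv)
    cm <- class_metrics(confusion_counts(pred$pred, ds$label))
    f1s[i] <- cm$f1[["1"]]
  }
  best <- lengths[which.max(f1s)]  # which.max takes the first (smallest) tie
  list(length = best, f1 = f1s)
}
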