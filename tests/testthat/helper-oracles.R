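# Independent oracles used across the suite. Pure R, deliberately naive:
# they enumerate or simulate rather than share any code path with the
# package internals they check.

# All walks of l steps from every non-isolated start, with probabilities
# (uniform start over non-isolated nodes, uniform neighbor steps).
# Returns the anonymous-pattern distribution as a named vector in the
# package's canonical pattern order.
brute_force_embedding <- function(adj, l) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] == 1))
  starts <- which(vapply(nbrs, length, 0L) > 0)
  pats <- enumerate_walk_patterns(l)
  out <- setNames(numeric(length(pats)), pattern_labels(pats))
  if (!length(starts)) return(out)
  walk_rec <- function(seq_nodes, prob) {
    if (length(seq_nodes) == l + 1) {
      lab <- paste(match(seq_nodes, unique(seq_nodes)), collapse = "-")
      out[lab] <<- out[lab] + prob
      return(invisible())
    }
    nb <- nbrs[[seq_nodes[length(seq_nodes)]]]
    for (nxt in nb) walk_rec(c(seq_nodes, nxt), prob / length(nb))
  }
  for (s in starts) walk_rec(s, 1 / length(starts))
  out
}

# Random symmetric 0/1 adjacency with zero diagonal.
random_adjacency <- function(n, p_edge) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
  adj
}

# CI as the average over all ordered pairs of distinct players of the
# indicator that both chose the same option.
brute_force_ci <- function(options_chosen) {
  n <- length(options_chosen)
  tot <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && options_chosen[i] == options_chosen[j]) tot <- tot + 1L
  tot / (n * (n - 1))
}

# Closed-form simple linear regression + Pearson correlation test.
closed_form_regression <- function(y, x) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(slope = b, intercept = a, r = r,
       p = 2 * pt(-abs(tstat), df = n - 2))
}

# Bell numbers via the Bell triangle.
bell_numbers <- function(k) {
  row <- 1
  out <- numeric(k)
  for (i in seq_len(k)) {
    out[i] <- row[length(row)]
    row <- cumsum(c(row[length(row)], row))
  }
  out
}

# Small helper: band-limited test epoch with a module structure.
module_epoch <- function(partition, n_channels, rho, fs = 512, n = 512,
                         noise_sd = 1) {
  cfg <- study_config(n_channels = n_channels, fs_raw = fs,
                      epoch_duration = n / fs, coupling = rho,
                      noise_sd = noise_sd, seed = 1L)
  synthesize_epoch(partition, cfg, seed = sample.int(2^31 - 1, 1))
}
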