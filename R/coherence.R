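#' Standard 16-electrode 10-20 montage labels
#'
#' Node order here defines node order in every downstream matrix and graph.
#'
#' @param n number of channels; labels beyond the 16 standard names are
#'   generated as `ch17, ch18, ...`.
#' @return Character vector of length `n`.
#' @export
montage_labels <- function(n = 16) {
  base <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
            "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6")
  if (n <= 16) base[seq_len(n)]
  else c(base, paste0("ch", 17:n))
}

#' Pairwise band-averaged coherence matrix
#'
#' Estimates the magnitude-squared coherence (MSC) between every channel
#' pair by Welch's method -- Hann-windowed segments with 50% overlap -- and
#' averages it over the frequency bins inside `band` to a single scalar in
#' \[0, 1\] per pair. With the defaults (64 samples at 64 Hz, 32-sample
#' segments) each pair is summarized from 3 segments over the 2-32 Hz bins.
#' MSC is invariant to channel sign and scale; the diagonal is 1 by
#' definition.
#'
#' @param epoch preprocessed [eeg_epoch()] (any rate; defaults assume 64 Hz).
#' @param band frequency band in Hz over which bins are averaged.
#' @param seg_length Welch segment length in samples.
#' @param overlap fractional segment overlap in \[0, 1).
#' @return `n x n` symmetric matrix of class `"coherence_matrix"` with
#'   montage dimnames, unit diagonal, entries in \[0, 1\].
#' @export
pairwise_coherence <- function(epoch, band = c(1, 32), seg_length = 32,
                               overlap = 0.5) {
  fs <- epoch_fs(epoch)
  x <- unclass(epoch)
  step <- max(1L, as.integer(round(seg_length * (1 - overlap))))
  starts <- seq(1L, ncol(x) - seg_length + 1L, by = step)
  if (ncol(x) < seg_length || length(starts) < 2L)
    stop("epoch too short for two Welch segments of length ", seg_length)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_length - 1)) / seg_length)  # Hann
  nch <- nrow(x)
  # segment spectra: [channel, segment, frequency bin]
  spec <- array(0+0i, c(nch, length(starts), seg_length))
  for (ci in seq_len(nch)) {
    for (si in seq_along(starts)) {
      seg <- x[ci, starts[si]:(starts[si] + seg_length - 1L)] * w
      spec[ci, si, ] <- stats::fft(seg)
    }
  }
  freqs <- (0:(seg_length - 1)) * fs / seg_length
  keep <- which(freqs >= band[1] & freqs <= min(band[2], fs / 2))
  pxx <- matrix(0, nch, length(keep))
  for (ci in seq_len(nch))
    pxx[ci, ] <- colSums(abs(matrix(spec[ci, , keep], length(starts)))^2)
  out <- diag(1, nch)
  for (i in seq_len(nch - 1L)) {
    for (j in (i + 1L):nch) {
      sxy <- colSums(matrix(spec[i, , keep] * Conj(spec[j, , keep]),
                            length(starts)))
      msc <- Mod(sxy)^2 / (pxx[i, ] * pxx[j, ])
      out[i, j] <- out[j, i] <- mean(msc)
    }
  }
  labels <- rownames(x)
  if (is.null(labels)) labels <- montage_labels(nch)
  dimnames(out) <- list(labels, labels)
  structure(out, class = c("coherence_matrix", "matrix", "array"))
}

#' Threshold a coherence matrix into a binary graph
#'
#' An edge joins channels i != j whenever their band-averaged coherence is
#' `>= threshold` (inclusive at the boundary). Self-loops are excluded: the
#' coherence of a signal with itself is always 1 and carries no information.
#' A 16-node graph has at most 120 edges and node degree at most 15.
#'
#' @param cohmat a `"coherence_matrix"` (or plain symmetric matrix in
#'   \[0, 1\]).
#' @param threshold synchronization cutoff in \[0, 1\]; default 0.5.
#' @return Binary adjacency matrix of class `"coherence_graph"`, symmetric
#'   with zero diagonal, labels preserved.
#' @examples
#' m <- matrix(0.6, 3, 3); diag(m) <- 1
#' sum(threshold_graph(m)) / 2    # 3 edges
#' @export
threshold_graph <- function(cohmat, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("`threshold` must lie in [0, 1]")
  m <- unclass(cohmat)
  adj <- (m >= threshold) * 1L
  diag(adj) <- 0L
  adj <- adj * t(adj)  # enforce symmetry defensively
  if (is.null(dimnames(adj)))
    dimnames(adj) <- list(montage_labels(nrow(adj)), montage_labels(nrow(adj)))
  structure(adj, class = c("coherence_graph", "matrix", "array"))
}

#' @export
print.coherence_graph <- function(x, ...) {
  cat(sprintf("Coherence graph: %d nodes, %d edges (max %d)\n",
              nrow(x), sum(x) / 2, nrow(x) * (nrow(x) - 1) / 2))
  invisible(x)
}

#' Edge list of a coherence graph
#'
#' @param graph a `"coherence_graph"` adjacency matrix.
#' @return `data.frame` with character columns `from`, `to` (one row per
#'   undirected edge, from-index < to-index in montage order); zero rows for
#'   an edgeless graph.
#' @export
graph_to_edgelist <- function(graph) {
  adj <- unclass(graph)
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  labels <- rownames(adj)
  data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Rebuild the adjacency matrix from an edge list
#'
#' Inverse of [graph_to_edgelist()] given the node label set.
#'
#' @param edges `data.frame` with columns `from`, `to`.
#' @param labels character vector of all node labels (defines node order).
#' @return A `"coherence_graph"` adjacency matrix.
#' @export
edgelist_to_graph <- function(edges, labels = montage_labels()) {
  adj <- matrix(0L, length(labels), length(labels),
                dimnames = list(labels, labels))
  if (nrow(edges)) {
    i <- match(edges$from, labels); j <- match(edges$to, labels)
    if (anyNA(i) || anyNA(j)) stop("edge labels not in `labels`")
    adj[cbind(i, j)] <- 1L
    adj[cbind(j, i)] <- 1L
  }
  structure(adj, class = c("coherence_graph", "matrix", "array"))
}
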