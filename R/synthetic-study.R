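#' Sample player choices for every game
#'
#' Draws each player's choice in each game independently from a single-focal
#' categorical distribution: option 1 (the focal point) has probability
#' `s_g + (1 - s_g)/n_options`, the other options share the remainder equally.
#' Higher saliency concentrates choices and raises the game's coordination
#' index.
#'
#' @param config a [study_config()].
#' @return An `n_players x n_games` integer matrix of options in
#'   `1:n_options`, with dimnames `player`/`game`.
#' @examples
#' ch <- sample_choices(study_config(saliency = 1, seed = 1))
#' all(ch == 1)   # unanimous focal choice
#' @export
sample_choices <- function(config) {
  validate_study_config(config)
  ch <- matrix(NA_integer_, config$n_players, config$n_games,
               dimnames = list(player = seq_len(config$n_players),
                               game = seq_len(config$n_games)))
  for (g in seq_len(config$n_games)) {
    s <- config$saliency[g]
    p <- rep((1 - s) / config$n_options, config$n_options)
    p[1] <- p[1] + s
    set.seed(derive_seed(config$seed, game = g, stage = 1L))
    ch[, g] <- sample.int(config$n_options, config$n_players,
                          replace = TRUE, prob = p)
  }
  ch
}

#' Tally one game's choices
#'
#' @param choices choice matrix from [sample_choices()].
#' @param game game index (column).
#' @return Integer vector of per-option counts `m_j`, summing to `n_players`.
#' @export
choice_tally <- function(choices, game) {
  opts <- choices[, game]
  tabulate(opts, nbins = max(opts))
}

#' Build latent connectivity templates
#'
#' For every (game, option) cell, partitions the channels into disjoint
#' modules of size >= 2 (plus possibly a singleton leftover). Channels in one
#' module will share a latent source in [synthesize_epoch()], so the
#' template is the ground-truth coherence structure: players who pick the
#' same option in a game get epochs generated from the same partition.
#' Different options of the same game are guaranteed partitions with
#' distinct block-size profiles, i.e. non-isomorphic clique structures:
#' the anonymous-walk embedding downstream is invariant under node
#' relabeling, so merely relabeled partitions would be indistinguishable
#' to it and the templates would carry no choice signal.
#'
#' @param config a [study_config()].
#' @return Nested list `templates[[game]][[option]]`, each a list of integer
#'   vectors (the modules) covering `1:n_channels`.
#' @export
build_templates <- function(config) {
  validate_study_config(config)
  templates <- vector("list", config$n_games)
  for (g in seq_len(config$n_games)) {
    set.seed(derive_seed(config$seed, game = g, stage = 2L))
    parts <- list()
    for (o in seq_len(config$n_options)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        part <- random_partition(config$n_channels)
        if (!partition_profile(part) %in% vapply(parts, partition_profile, ""))
          break
        # few channels can exhaust the distinct size profiles; fall back to
        # distinct labeled partitions after enough failed draws
        if (tries > 200L &&
            !partition_key(part) %in% vapply(parts, partition_key, ""))
          break
      }
      parts[[o]] <- part
    }
    templates[[g]] <- parts
  }
  templates
}

# Random partition of 1:n into shuffled blocks of size 2-6 (leftover of 1
# becomes a singleton). The wide size range gives many distinct block-size
# profiles, so build_templates() can draw non-isomorphic partitions.
random_partition <- function(n) {
  perm <- sample.int(n)
  blocks <- list()
  i <- 1L
  while (n - i + 1L >= 2L) {
    size <- min(sample(2:6, 1L), n - i + 1L)
    if (n - i + 1L - size == 1L) size <- size + 1L  # avoid stranding one
    size <- min(size, n - i + 1L)
    blocks[[length(blocks) + 1L]] <- sort(perm[i:(i + size - 1L)])
    i <- i + size
  }
  if (i <= n) blocks[[length(blocks) + 1L]] <- perm[n]
  blocks
}

# Canonical labeled form ("which channels together").
partition_key <- function(part) {
  paste(sort(vapply(part, function(b) paste(b, collapse = ","), "")),
        collapse = "|")
}

# Unlabeled form: the sorted multiset of block sizes, which is what an
# isomorphism-invariant graph embedding can distinguish.
partition_profile <- function(part) {
  paste(sort(lengths(part)), collapse = ",")
}

#' Synthesize one raw EEG epoch from a module partition
#'
#' Each module m carries one latent band-limited (1-32 Hz) Gaussian source
#' z_m; channel i in module m is `sqrt(rho) z_m + sqrt(1 - rho) noise_sd n_i`
#' with independent band-limited noise n_i. Singleton channels are pure
#' noise. Intra-module coherence therefore increases with rho while
#' inter-module coherence does not depend on it.
#'
#' @param partition list of integer vectors (modules), as one cell of
#'   [build_templates()].
#' @param config a [study_config()].
#' @param seed optional integer seed for this epoch's stream; defaults to the
#'   master seed.
#' @return An [eeg_epoch()]: `n_channels x (fs_raw * epoch_duration)` matrix.
#' @export
synthesize_epoch <- function(partition, config, seed = config$seed) {
  validate_study_config(config)
  n_samp <- round(config$fs_raw * config$epoch_duration)
  set.seed(seed)
  rho <- config$coupling
  x <- matrix(0, config$n_channels, n_samp)
  for (mod in partition) {
    z <- bandlimited_noise(n_samp, config$fs_raw)
    for (ch in mod) {
      n_i <- bandlimited_noise(n_samp, config$fs_raw)
      x[ch, ] <- if (length(mod) >= 2L)
        sqrt(rho) * z + sqrt(1 - rho) * config$noise_sd * n_i
      else config$noise_sd * n_i
    }
  }
  eeg_epoch(x, fs = config$fs_raw)
}

# White Gaussian series band-passed to 1-32 Hz so that the preprocessing
# chain is approximately transparent to it.
bandlimited_noise <- function(n, fs, band = c(1, 32)) {
  w <- rnorm(n)
  if (n < 24) return(w)  # too short to filter stably; tests only
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, w))
}

#' Generate a full synthetic study
#'
#' Draws choices, builds latent templates, and synthesizes one raw epoch per
#' (player, game) from the partition of that player's chosen option. With
#' the default configuration this yields 10 x 12 = 120 epochs. Identical
#' configuration (including seed) reproduces the bundle bit for bit.
#'
#' @param config a [study_config()].
#' @return An object of class `"coord_study"`: list with elements `config`,
#'   `choices` (players x games), `templates`, and `epochs` (list indexed
#'   `[[player]][[game]]` of [eeg_epoch()] objects).
#' @examples
#' study <- generate_study(study_config(n_players = 3, n_games = 2, seed = 7))
#' length(unlist(study$epochs, recursive = FALSE))  # 6 epochs
#' @export
generate_study <- function(config) {
  validate_study_config(config)
  choices <- sample_choices(config)
  templates <- build_templates(config)
  epochs <- vector("list", config$n_players)
  for (p in seq_len(config$n_players)) {
    epochs[[p]] <- vector("list", config$n_games)
    for (g in seq_len(config$n_games)) {
      part <- templates[[g]][[choices[p, g]]]
      epochs[[p]][[g]] <- synthesize_epoch(
        part, config, seed = derive_seed(config$seed, p, g, stage = 3L))
    }
  }
  structure(list(config = config, choices = choices, templates = templates,
                 epochs = epochs),
            class = "coord_study")
}

#' @export
print.coord_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic coordination study: %d players x %d games = %d epochs\n",
              cfg$n_players, cfg$n_games, cfg$n_players * cfg$n_games))
  cat(sprintf("  %d channels @ %g Hz, rho = %g\n",
              cfg$n_channels, cfg$fs_raw, cfg$coupling))
  ci <- ci_table(x$choices)
  cat(sprintf("  per-game CI: min %.3f, median %.3f, max %.3f\n",
              min(ci$ci), stats::median(ci$ci), max(ci$ci)))
  invisible(x)
}
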