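#' Configuration of a synthetic tacit-coordination study
#'
#' Bundles every knob of the synthetic-study generator. The defaults mirror
#' the design of the motivating experiment: 10 players, 12 coordination games
#' with four options each, 16 EEG channels sampled at 512 Hz, 1 s epochs.
#'
#' @param n_players number of players (>= 2).
#' @param n_games number of coordination games (>= 2).
#' @param n_options number of choice options per game (>= 2).
#' @param n_channels number of EEG channels (>= 4).
#' @param fs_raw raw sampling rate in Hz.
#' @param epoch_duration epoch length in seconds.
#' @param saliency per-game focal-point saliency, each in \[0, 1\]. The focal
#'   option (option 1) is chosen with probability `s + (1 - s)/n_options`;
#'   the remaining options share the rest equally. `s = 0` is a uniform
#'   choice, `s = 1` unanimity. A scalar is recycled to `n_games`.
#' @param coupling shared-source variance fraction rho in \[0, 1\]: channels in
#'   the same latent module carry `sqrt(rho)` of a common band-limited source.
#'   Intra-module magnitude-squared coherence grows with rho (~ rho^2 for unit
#'   noise); rho = 0 makes all channels independent.
#' @param noise_sd scale of the per-channel additive band-limited noise.
#' @param seed master RNG seed (integer); all per-(player, game) streams are
#'   derived from it deterministically.
#'
#' @return An object of class `"study_config"` (a validated list).
#' @examples
#' cfg <- study_config(seed = 42)
#' cfg$n_players * cfg$n_games   # 120 epochs
#' @export
study_config <- function(n_players = 10, n_games = 12, n_options = 4,
                         n_channels = 16, fs_raw = 512, epoch_duration = 1.0,
                         saliency = seq(0, 0.5, length.out = n_games),
                         coupling = 0.9, noise_sd = 1, seed = 1L) {
  if (length(saliency) == 1L) saliency <- rep(saliency, n_games)
  cfg <- list(n_players = as.integer(n_players), n_games = as.integer(n_games),
              n_options = as.integer(n_options),
              n_channels = as.integer(n_channels),
              fs_raw = fs_raw, epoch_duration = epoch_duration,
              saliency = as.numeric(saliency), coupling = coupling,
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_study_config(cfg)
  class(cfg) <- "study_config"
  cfg
}

validate_study_config <- function(cfg) {
  stopifnot(cfg$n_players >= 2, cfg$n_games >= 2, cfg$n_options >= 2,
            cfg$n_channels >= 4, cfg$fs_raw > 0, cfg$epoch_duration > 0)
  if (length(cfg$saliency) != cfg$n_games)
    stop("`saliency` must have length n_games (", cfg$n_games, ")")
  if (any(cfg$saliency < 0 | cfg$saliency > 1))
    stop("`saliency` values must lie in [0, 1]")
  if (cfg$coupling < 0 || cfg$coupling > 1)
    stop("`coupling` (rho) must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0")
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Synthetic coordination-study configuration\n")
  cat(sprintf("  %d players x %d games (%d options), %d channels @ %g Hz, %g s epochs\n",
              x$n_players, x$n_games, x$n_options, x$n_channels, x$fs_raw,
              x$epoch_duration))
  cat(sprintf("  saliency: %s\n", paste(format(x$saliency, digits = 3),
                                        collapse = " ")))
  cat(sprintf("  coupling rho = %g, noise_sd = %g, seed = %d\n",
              x$coupling, x$noise_sd, x$seed))
  invisible(x)
}

# Deterministic per-(player, game, stage) substream seed below 2^31.
# stage separates choice/template/epoch streams from one master seed.
derive_seed <- function(master, player = 0L, game = 0L, stage = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  for (k in c(stage, player, game)) {
    s <- (s * 69069 + 1234567 + as.numeric(k) * 97003) %% m
  }
  as.integer(s)
}
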