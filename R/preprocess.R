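#' EEG epoch container
#'
#' A thin wrapper around a channels-by-samples numeric matrix carrying its
#' sampling rate (and optional player/game identifiers) as attributes.
#'
#' @param data numeric matrix, channels x samples, finite values.
#' @param fs sampling rate in Hz.
#' @param player,game optional identifiers.
#' @return Object of class `"eeg_epoch"`.
#' @export
eeg_epoch <- function(data, fs, player = NULL, game = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), all(is.finite(data)), fs > 0)
  structure(data, fs = fs, player = player, game = game,
            class = c("eeg_epoch", "matrix", "array"))
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("EEG epoch: %d channels x %d samples @ %g Hz (%.3g s)\n",
              nrow(x), ncol(x), attr(x, "fs"), ncol(x) / attr(x, "fs")))
  invisible(x)
}

epoch_fs <- function(epoch) {
  fs <- attr(epoch, "fs")
  if (is.null(fs)) stop("epoch carries no sampling rate; use eeg_epoch()")
  fs
}

# rebuild an epoch keeping identifiers, possibly with a new rate
reshape_epoch <- function(template, data, fs = epoch_fs(template)) {
  eeg_epoch(unclass(data), fs = fs,
            player = attr(template, "player"), game = attr(template, "game"))
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward ([signal::filtfilt()]), so
#' the pass band is preserved with no group delay. Default band 1-32 Hz
#' covers the delta through beta rhythms.
#'
#' @param epoch an [eeg_epoch()].
#' @param low,high band edges in Hz; `0 < low < high < fs/2` required.
#' @return Filtered epoch, same shape and rate.
#' @export
bandpass <- function(epoch, low = 1, high = 32) {
  fs <- epoch_fs(epoch)
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("`high` must be below the Nyquist rate ", fs / 2, " Hz")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(unclass(epoch), 1L, function(ch)
    as.numeric(signal::filtfilt(bf, ch))))
  reshape_epoch(epoch, out)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' each column (time point) of the output sums to zero.
#'
#' @param epoch an [eeg_epoch()] with >= 2 channels.
#' @return Re-referenced epoch.
#' @export
rereference_average <- function(epoch) {
  if (nrow(epoch) < 2L) stop("average reference needs >= 2 channels")
  reshape_epoch(epoch, sweep(unclass(epoch), 2L, colMeans(epoch)))
}

#' Baseline correction over the full epoch
#'
#' Subtracts each channel's temporal mean. With no pre-stimulus segment in
#' the synthetic design the whole epoch serves as the baseline window.
#'
#' @param epoch an [eeg_epoch()].
#' @return Epoch with zero-mean channels.
#' @export
baseline_correct <- function(epoch) {
  reshape_epoch(epoch, sweep(unclass(epoch), 1L, rowMeans(epoch)))
}

#' Downsample by an integer factor
#'
#' Anti-alias filters ([signal::decimate()], 8th-order Chebyshev type I
#' applied forward-backward) and decimates each channel. The raw rate must
#' be an integer multiple of `fs_out`.
#'
#' @param epoch an [eeg_epoch()].
#' @param fs_out target rate in Hz.
#' @return Epoch at `fs_out` with `samples * fs_out / fs` columns.
#' @export
downsample <- function(epoch, fs_out = 64) {
  fs <- epoch_fs(epoch)
  q <- fs / fs_out
  if (abs(q - round(q)) > 1e-9) stop("fs (", fs, ") must be an integer multiple of fs_out")
  q <- as.integer(round(q))
  if (q == 1L) return(epoch)
  out <- t(apply(unclass(epoch), 1L, function(ch)
    as.numeric(signal::decimate(ch, q))))
  reshape_epoch(epoch, out, fs = fs_out)
}

#' Full preprocessing chain
#'
#' Applies, in order: band-pass (default 1-32 Hz) -> artifact hook (identity
#' by default; slot for ICA-style cleaning on real recordings) -> common
#' average reference -> baseline correction -> downsampling (default to
#' 64 Hz), then crops to the first `window` seconds. With the defaults a
#' 16 x 512 raw epoch becomes a 16 x 64 analysis window.
#'
#' @param epoch raw [eeg_epoch()] of at least `window` seconds.
#' @param band band-pass edges in Hz.
#' @param fs_out target sampling rate in Hz.
#' @param window analysis window length in seconds.
#' @param artifact_hook function `epoch -> epoch` applied after filtering;
#'   identity by default (the synthetic generator produces no artifacts).
#' @return Preprocessed epoch, `n_channels x (fs_out * window)`.
#' @examples
#' ep <- eeg_epoch(matrix(rnorm(16 * 512), 16), fs = 512)
#' dim(preprocess_epoch(ep))   # 16 64
#' @export
preprocess_epoch <- function(epoch, band = c(1, 32), fs_out = 64,
                             window = 1.0, artifact_hook = identity) {
  fs <- epoch_fs(epoch)
  if (ncol(epoch) < fs * window)
    stop("epoch shorter than the ", window, " s analysis window")
  out <- bandpass(epoch, band[1], band[2])
  out <- artifact_hook(out)
  out <- rereference_average(out)
  out <- baseline_correct(out)
  out <- downsample(out, fs_out)
  n_keep <- round(fs_out * window)
  reshape_epoch(out, unclass(out)[, seq_len(n_keep), drop = FALSE],
                fs = fs_out)
}
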