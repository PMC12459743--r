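#' Epoched multichannel signal container
#'
#' Bundles a trials x channels x samples array with its sampling rate and
#' time axis. Sensor-level data are in microvolts; source-level time courses
#' are in arbitrary units.
#'
#' @param data numeric array, trials x channels x samples.
#' @param fs_hz sampling rate in Hz.
#' @param t0_ms time of the first sample relative to stimulus onset (ms).
#' @param channel_names character vector, one per channel.
#' @param trial_indices integer vector aligning trials with a task design.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs_hz, t0_ms = 0,
                       channel_names = NULL, trial_indices = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, is.numeric(fs_hz), fs_hz > 0)
  if (any(!is.finite(data))) stop("epoch data must be finite (no NaN/Inf)")
  n_tr <- dim(data)[1]; n_ch <- dim(data)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  if (is.null(trial_indices)) trial_indices <- seq_len(n_tr)
  stopifnot(length(channel_names) == n_ch, length(trial_indices) == n_tr)
  structure(list(data = data, fs_hz = fs_hz, t0_ms = t0_ms,
                 channel_names = as.character(channel_names),
                 trial_indices = as.integer(trial_indices)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, t0 = %g ms\n",
              d[1], d[2], d[3], x$fs_hz, x$t0_ms))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Time axis of an epoched signal, in milliseconds
#' @param x an `eeg_epochs` object.
#' @return numeric vector of sample times relative to stimulus onset.
#' @export
epoch_times_ms <- function(x) {
  stopifnot(inherits(x, "eeg_epochs"))
  x$t0_ms + (seq_len(dim(x$data)[3]) - 1) * 1000 / x$fs_hz
}

#' Continuous multichannel signal container
#'
#' @param data numeric matrix, channels x samples.
#' @param fs_hz sampling rate in Hz.
#' @param channel_names character vector, one per channel.
#' @return An object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, fs_hz, channel_names = NULL) {
  stopifnot(is.matrix(data), is.numeric(fs_hz), fs_hz > 0)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(channel_names) == nrow(data))
  structure(list(data = data, fs_hz = fs_hz,
                 channel_names = as.character(channel_names)),
            class = "eeg_continuous")
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat(sprintf("<eeg_continuous> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz))
  invisible(x)
}
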