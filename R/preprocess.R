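#' @importFrom signal butter filtfilt fir1 fftfilt resample
NULL

apply_channelwise <- function(x, f) {
  if (inherits(x, "eeg_continuous")) {
    out <- x
    for (ch in seq_len(nrow(x$data))) out$data[ch, ] <- f(x$data[ch, ])
    out
  } else if (inherits(x, "eeg_epochs")) {
    out <- x
    d <- dim(x$data)
    for (tr in seq_len(d[1])) for (ch in seq_len(d[2]))
      out$data[tr, ch, ] <- f(x$data[tr, ch, ])
    out
  } else if (is.numeric(x)) {
    f(x)
  } else stop("unsupported signal type")
}

signal_fs <- function(x, fs_hz) {
  if (inherits(x, c("eeg_continuous", "eeg_epochs"))) x$fs_hz
  else if (!is.null(fs_hz)) fs_hz
  else stop("fs_hz required for plain numeric input")
}

#' Downsample a signal with anti-alias filtering
#'
#' Rational-ratio polyphase resampling; the anti-alias low-pass is part of
#' the polyphase design. Upsampling is refused.
#'
#' @param x `eeg_continuous`, `eeg_epochs`, or numeric vector.
#' @param target_fs_hz new sampling rate, must not exceed the current rate.
#' @param fs_hz current rate (numeric-vector input only).
#' @return the signal resampled to `target_fs_hz`.
#' @export
downsample <- function(x, target_fs_hz, fs_hz = NULL) {
  fs <- signal_fs(x, fs_hz)
  if (target_fs_hz > fs) stop("no upsampling: target_fs (", target_fs_hz,
                              ") exceeds current fs (", fs, ")")
  if (target_fs_hz == fs) return(x)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  ip <- round(target_fs_hz); iq <- round(fs)
  if (abs(ip - target_fs_hz) > 1e-9 || abs(iq - fs) > 1e-9)
    stop("sampling rates must be integers for rational resampling")
  d <- g(ip, iq)
  p <- ip / d; q <- iq / d
  res <- apply_channelwise_resample(x, p, q, target_fs_hz)
  res
}

apply_channelwise_resample <- function(x, p, q, new_fs) {
  rs <- function(v) as.numeric(signal::resample(v, p, q))
  if (inherits(x, "eeg_continuous")) {
    rows <- lapply(seq_len(nrow(x$data)), function(ch) rs(x$data[ch, ]))
    eeg_continuous(do.call(rbind, rows), new_fs, x$channel_names)
  } else if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)
    n_new <- length(rs(x$data[1, 1, ]))
    out <- array(0, dim = c(d[1], d[2], n_new))
    for (tr in seq_len(d[1])) for (ch in seq_len(d[2]))
      out[tr, ch, ] <- rs(x$data[tr, ch, ])
    eeg_epochs(out, new_fs, x$t0_ms, x$channel_names, x$trial_indices)
  } else rs(x)
}

#' Broadband band-pass and mains-notch filtering
#'
#' Recursive (Butterworth) band-pass applied forward-backward, giving an
#' effective 48 dB/octave roll-off from the 4th-order design, plus a narrow
#' band-stop around the mains frequency.
#'
#' @param x `eeg_continuous`, `eeg_epochs`, or numeric vector.
#' @param low_hz,high_hz pass-band edges in Hz (defaults 0.5 and 40).
#' @param notch_hz mains frequency to suppress (default 50; `NA` disables).
#' @param fs_hz sampling rate (numeric-vector input only).
#' @return the filtered signal, same container as the input.
#' @export
broadband_filter <- function(x, low_hz = 0.5, high_hz = 40, notch_hz = 50,
                             fs_hz = NULL) {
  fs <- signal_fs(x, fs_hz)
  nyq <- fs / 2
  if (low_hz <= 0 || high_hz >= nyq || low_hz >= high_hz)
    stop("band edges must satisfy 0 < low < high < fs/2")
  bp <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  nf <- if (!is.na(notch_hz) && notch_hz < nyq)
    signal::butter(2, c(notch_hz - 2, notch_hz + 2) / nyq, type = "stop")
  else NULL
  apply_channelwise(x, function(v) {
    y <- signal::filtfilt(bp, v)
    if (!is.null(nf)) y <- signal::filtfilt(nf, y)
    y
  })
}

#' Hamming-windowed sinc FIR band extraction
#'
#' Extracts a narrow oscillatory band with a linear-phase FIR filter designed
#' by the window method (Hamming). The filter order follows from a transition
#' width of 25% of the lower band edge; the group delay is compensated
#' exactly, so the output is effectively zero-phase.
#'
#' @param x `eeg_continuous`, `eeg_epochs`, or numeric vector.
#' @param band either a length-2 numeric (Hz) or one of `"theta"` (4-7 Hz),
#'   `"alpha"` (8-12 Hz).
#' @param fs_hz sampling rate (numeric-vector input only).
#' @return the band-limited signal, same container as the input.
#' @export
narrowband_extract <- function(x, band = "alpha", fs_hz = NULL) {
  fs <- signal_fs(x, fs_hz)
  if (is.character(band))
    band <- switch(band, theta = c(4, 7), alpha = c(8, 12),
                   stop("unknown band name: ", band))
  stopifnot(length(band) == 2, band[1] < band[2])
  nyq <- fs / 2
  if (band[1] <= 0 || band[2] >= nyq)
    stop("band must lie strictly inside (0, fs/2)")
  trans_hz <- 0.25 * band[1]
  n_ord <- ceiling(3.3 * fs / trans_hz)        # Hamming main-lobe rule
  if (n_ord %% 2 == 1) n_ord <- n_ord + 1      # even order -> integer group delay
  b <- signal::fir1(n_ord, band / nyq, type = "pass")
  gd <- n_ord / 2
  apply_channelwise(x, function(v) {
    y <- signal::fftfilt(b, c(v, numeric(gd)))
    y[(gd + 1):(gd + length(v))]
  })
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over the retained channels, so the
#' retained-channel average becomes identically zero.
#'
#' @param x `eeg_continuous` or `eeg_epochs`.
#' @param excluded_channels channel names left out of the average (they are
#'   still re-referenced).
#' @return the re-referenced signal.
#' @export
common_average_reference <- function(x, excluded_channels = character()) {
  nm <- x$channel_names
  keep <- !(nm %in% excluded_channels)
  if (sum(keep) < 2) stop("common average needs at least 2 retained channels")
  if (inherits(x, "eeg_continuous")) {
    ref <- colMeans(x$data[keep, , drop = FALSE])
    x$data <- sweep(x$data, 2, ref)
  } else if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)
    for (tr in seq_len(d[1])) {
      slab <- matrix(x$data[tr, , ], nrow = d[2])   # channels x samples
      ref <- colMeans(slab[keep, , drop = FALSE])
      x$data[tr, , ] <- sweep(slab, 2, ref)
    }
  } else stop("unsupported signal type")
  x
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Cuts a half-open window `[window_ms[1], window_ms[2])` around each event.
#' Events whose window is not fully inside the recording are dropped and
#' reported.
#'
#' @param continuous an `eeg_continuous`.
#' @param event_samples 1-based sample indices of stimulus onsets.
#' @param window_ms length-2 window relative to onset, default
#'   `c(-2000, 2000)`.
#' @return an `eeg_epochs`; dropped event indices are in attribute
#'   `"dropped_events"`.
#' @export
epoch_segments <- function(continuous, event_samples,
                           window_ms = c(-2000, 2000)) {
  stopifnot(inherits(continuous, "eeg_continuous"), length(window_ms) == 2,
            window_ms[1] < window_ms[2])
  fs <- continuous$fs_hz
  n_total <- ncol(continuous$data)
  n_samp <- round((window_ms[2] - window_ms[1]) * fs / 1000)
  off0 <- round(window_ms[1] * fs / 1000)
  starts <- as.integer(event_samples) + off0
  ok <- starts >= 1 & (starts + n_samp - 1) <= n_total
  dropped <- which(!ok)
  if (!any(ok)) {
    warning("no event has full window support; returning empty epochs")
    arr <- array(0, dim = c(0, nrow(continuous$data), n_samp))
    out <- eeg_epochs(arr, fs, window_ms[1], continuous$channel_names,
                      integer(0))
    attr(out, "dropped_events") <- dropped
    return(out)
  }
  kept <- which(ok)
  arr <- array(0, dim = c(length(kept), nrow(continuous$data), n_samp))
  for (i in seq_along(kept)) {
    s <- starts[kept[i]]
    arr[i, , ] <- continuous$data[, s:(s + n_samp - 1)]
  }
  out <- eeg_epochs(arr, fs, window_ms[1], continuous$channel_names, kept)
  attr(out, "dropped_events") <- dropped
  out
}

#' Automatic amplitude-based epoch rejection
#'
#' A trial is rejected when any channel shows (a) a peak-to-peak excursion
#' above `max_pp_uv` inside any sliding window of `max_pp_window_ms`
#' ("max-diff"), or (b) a peak-to-peak span below `flat_pp_uv` inside any
#' sliding window of `flat_window_ms` ("flatline"). Sliding windows step one
#' sample.
#'
#' @param epochs an `eeg_epochs` in uV.
#' @param max_pp_uv,max_pp_window_ms amplitude rule (defaults 200 uV / 200 ms).
#' @param flat_pp_uv,flat_window_ms flatline rule (defaults 0.5 uV / 100 ms).
#' @return list with `epochs` (kept trials), `rejected` (logical per input
#'   trial) and `report` (data frame: trial, reason, channel,
#'   window_start_ms).
#' @export
reject_epochs <- function(epochs, max_pp_uv = 200, max_pp_window_ms = 200,
                          flat_pp_uv = 0.5, flat_window_ms = 100) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  fs <- epochs$fs_hz
  w_max <- round(max_pp_window_ms * fs / 1000)
  w_flat <- round(flat_window_ms * fs / 1000)
  if (w_max > d[3] || w_flat > d[3])
    stop("rejection window longer than the epoch")
  rejected <- logical(d[1])
  rep_list <- list()
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      v <- epochs$data[tr, ch, ]
      pp_max <- zoo::rollmax(v, w_max) + zoo::rollmax(-v, w_max)
      if (any(pp_max > max_pp_uv)) {
        pos <- which(pp_max > max_pp_uv)[1]
        rejected[tr] <- TRUE
        rep_list[[length(rep_list) + 1]] <- data.frame(
          trial = tr, reason = "max-diff", channel = epochs$channel_names[ch],
          window_start_ms = epochs$t0_ms + (pos - 1) * 1000 / fs)
        break
      }
      pp_flat <- zoo::rollmax(v, w_flat) + zoo::rollmax(-v, w_flat)
      if (any(pp_flat < flat_pp_uv)) {
        pos <- which(pp_flat < flat_pp_uv)[1]
        rejected[tr] <- TRUE
        rep_list[[length(rep_list) + 1]] <- data.frame(
          trial = tr, reason = "flatline", channel = epochs$channel_names[ch],
          window_start_ms = epochs$t0_ms + (pos - 1) * 1000 / fs)
        break
      }
    }
  }
  report <- if (length(rep_list)) do.call(rbind, rep_list)
  else data.frame(trial = integer(), reason = character(),
                  channel = character(), window_start_ms = numeric())
  keep <- which(!rejected)
  kept <- eeg_epochs(epochs$data[keep, , , drop = FALSE], fs, epochs$t0_ms,
                     epochs$channel_names, epochs$trial_indices[keep])
  list(epochs = kept, rejected = rejected, report = report)
}
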