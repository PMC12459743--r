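#' Project source time courses to sensors through a gain matrix
#'
#' Forward model for the synthetic pipeline: `sensors = mixing %*% sources +
#' noise`, with i.i.d. Gaussian sensor noise. Works on a continuous L x M
#' source matrix (returning an `eeg_continuous`) or on an `eeg_epochs` object
#' whose channels are sources (returning sensor epochs).
#'
#' @param sources L x M numeric matrix (samples x sources) or `eeg_epochs`.
#' @param mixing sensors x sources gain matrix; a warning is issued when it
#'   is column-rank deficient (source recovery is then not guaranteed).
#' @param sensor_noise_sd noise SD in the sensor units (uV).
#' @param seed integer seed for the noise.
#' @param fs_hz sampling rate recorded on the output when `sources` is a
#'   plain matrix.
#' @return `eeg_continuous` (matrix input) or `eeg_epochs` (epoched input),
#'   with the mixing matrix attached as attribute `"mixing"`.
#' @export
mix_to_sensors <- function(sources, mixing, sensor_noise_sd = 0, seed = 1,
                           fs_hz = 256) {
  stopifnot(is.matrix(mixing), sensor_noise_sd >= 0)
  if (qr(mixing)$rank < ncol(mixing))
    warning("mixing matrix is column-rank deficient; source recovery is not guaranteed")
  set.seed(seed)
  if (inherits(sources, "eeg_epochs")) {
    d <- dim(sources$data)
    stopifnot(ncol(mixing) == d[2])
    out <- array(0, dim = c(d[1], nrow(mixing), d[3]))
    for (tr in seq_len(d[1]))
      out[tr, , ] <- mixing %*% sources$data[tr, , ]
    if (sensor_noise_sd > 0)
      out <- out + array(stats::rnorm(length(out), sd = sensor_noise_sd), dim = dim(out))
    res <- eeg_epochs(out, sources$fs_hz, sources$t0_ms,
                      channel_names = paste0("sensor", seq_len(nrow(mixing))),
                      trial_indices = sources$trial_indices)
  } else {
    stopifnot(is.matrix(sources), ncol(mixing) == ncol(sources))
    y <- sources %*% t(mixing)
    if (sensor_noise_sd > 0)
      y <- y + matrix(stats::rnorm(length(y), sd = sensor_noise_sd),
                      nrow(y), ncol(y))
    res <- eeg_continuous(t(y), fs_hz,
                          channel_names = paste0("sensor", seq_len(nrow(mixing))))
  }
  attr(res, "mixing") <- mixing
  res
}

#' Inject amplitude artifacts into epoched data
#'
#' Plants threshold-relevant artifacts for testing the automatic rejection
#' stage: `spike` adds a brief high-amplitude transient (so the peak-to-peak
#' excursion within a 200 ms window exceeds `amplitude_uv`), `flatline`
#' replaces a window with a constant value (span < 0.5 uV).
#'
#' @param epochs an `eeg_epochs` in uV.
#' @param spec data frame with columns `trial`, `kind` ("spike"/"flatline"),
#'   `amplitude_uv`, `duration_ms`.
#' @param seed integer seed for artifact placement.
#' @return list with `epochs` (modified copy) and `bad_trials` (sorted unique
#'   trial numbers that received an artifact).
#' @export
inject_artifacts <- function(epochs, spec, seed = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (nrow(spec) == 0) return(list(epochs = epochs, bad_trials = integer(0)))
  stopifnot(all(c("trial", "kind", "amplitude_uv", "duration_ms") %in% names(spec)))
  if (any(spec$trial < 1 | spec$trial > d[1]))
    stop("artifact spec targets a trial outside the epochs")
  n_samp_epoch <- d[3]
  set.seed(seed)
  out <- epochs$data
  for (r in seq_len(nrow(spec))) {
    w <- max(1L, round(spec$duration_ms[r] * epochs$fs_hz / 1000))
    if (w > n_samp_epoch)
      stop("artifact duration exceeds the epoch length")
    ch <- sample.int(d[2], 1)
    start <- sample.int(n_samp_epoch - w + 1, 1)
    idx <- start:(start + w - 1)
    tr <- spec$trial[r]
    if (spec$kind[r] == "spike") {
      pulse <- spec$amplitude_uv[r] * exp(-0.5 * ((seq_len(w) - (w + 1) / 2) / (w / 6))^2)
      out[tr, ch, idx] <- out[tr, ch, idx] + pulse
    } else if (spec$kind[r] == "flatline") {
      out[tr, ch, idx] <- mean(out[tr, ch, idx])
    } else stop("unknown artifact kind: ", spec$kind[r])
  }
  list(epochs = eeg_epochs(out, epochs$fs_hz, epochs$t0_ms,
                           epochs$channel_names, epochs$trial_indices),
       bad_trials = sort(unique(as.integer(spec$trial))))
}

#' Cut a continuous multichannel series into fixed-length pseudo-trials
#'
#' Utility for driving the epoched pipeline from a continuous simulation:
#' consecutive non-overlapping segments become trials.
#'
#' @param x an `eeg_continuous` or samples x channels matrix.
#' @param n_trials number of segments.
#' @param samples_per_trial segment length in samples.
#' @param fs_hz sampling rate (matrix input only).
#' @param t0_ms epoch time origin (default 0).
#' @return an `eeg_epochs`.
#' @export
segment_into_trials <- function(x, n_trials, samples_per_trial,
                                fs_hz = NULL, t0_ms = 0) {
  if (inherits(x, "eeg_continuous")) {
    m <- t(x$data); fs_hz <- x$fs_hz; nm <- x$channel_names
  } else {
    stopifnot(is.matrix(x), !is.null(fs_hz)); m <- x
    nm <- colnames(m)
  }
  need <- n_trials * samples_per_trial
  if (nrow(m) < need)
    stop("series too short: ", nrow(m), " samples < ", need)
  arr <- array(0, dim = c(n_trials, ncol(m), samples_per_trial))
  for (tr in seq_len(n_trials)) {
    seg <- m[((tr - 1) * samples_per_trial + 1):(tr * samples_per_trial), , drop = FALSE]
    arr[tr, , ] <- t(seg)
  }
  eeg_epochs(arr, fs_hz, t0_ms, channel_names = nm)
}
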