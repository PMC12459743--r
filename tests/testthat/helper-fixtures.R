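# Shared fixtures. Heavy simulations are cached per test run so several
# test files can reuse them without re-simulating.

b1_cache <- new.env()

b1_sim <- function(L = 4000, seed = 1) {
  key <- paste0("L", L, "_s", seed)
  if (is.null(b1_cache[[key]]))
    b1_cache[[key]] <- simulate_nmvar(benchmark_b1(), L, seed = seed)
  b1_cache[[key]]
}

# small linear MVAR(2) system with strong coefficients (joint simulation,
# raw scale) used by several linear-oracle tests
linear_mvar2 <- function() {
  A <- array(0, dim = c(3, 3, 2))
  A[1, 1, 1] <- 0.6
  A[2, 2, 1] <- 0.5
  A[3, 3, 1] <- 0.45
  A[2, 1, 1] <- 0.45          # edge 1 -> 2
  A[3, 2, 2] <- 0.40          # edge 2 -> 3 at lag 2
  nmvar_system(A, list(), innovation_sd = c(1, 1, 1), burn_in = 200,
               standardize_parents = FALSE)
}

# Bartlett standard deviation of the sample cross-correlation of two
# independent autocorrelated series (the white-noise 1/sqrt(L) bound does
# not apply to narrowband signals)
bartlett_sd <- function(x, y, K = 200) {
  r1 <- acf(x, lag.max = K, plot = FALSE)$acf[-1]
  r2 <- acf(y, lag.max = K, plot = FALSE)$acf[-1]
  sqrt((1 + 2 * sum(r1 * r2)) / length(x))
}

# epochs filled with smooth low-amplitude signal, in uV
quiet_epochs <- function(n_trials = 10, n_channels = 4, fs = 256,
                         dur_s = 2, amp = 25, seed = 42) {
  set.seed(seed)
  n <- fs * dur_s
  t <- (0:(n - 1)) / fs
  arr <- array(0, dim = c(n_trials, n_channels, n))
  for (tr in seq_len(n_trials)) for (ch in seq_len(n_channels))
    arr[tr, ch, ] <- amp * sin(2 * pi * stats::runif(1, 5, 12) * t +
                                 stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(n, sd = 2)
  eeg_epochs(arr, fs, t0_ms = -1000)
}

# smoothed-periodogram peak frequency of a vector
peak_freq <- function(x, fs, spans = NULL) {
  if (is.null(spans)) spans <- if (length(x) > 4096) c(11, 11) else NULL
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0, detrend = TRUE, spans = spans)
  sp$freq[which.max(sp$spec)]
}

rms <- function(x) sqrt(mean(x^2))
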