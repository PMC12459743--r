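test_that("downsampling preserves in-band content and sample arithmetic", {
  fs0 <- 500
  t <- (0:(fs0 * 8 - 1)) / fs0
  x <- sin(2 * pi * 10 * t)
  y <- downsample(x, 256, fs_hz = fs0)
  expect_lt(abs(peak_freq(y, 256) - 10), 0.2)
  # 4000 ms epoch: 500 Hz * 4 s = 2000 samples -> 1024 at 256 Hz
  cont <- eeg_continuous(matrix(x[1:2000], 1), fs0)
  out <- downsample(cont, 256)
  expect_equal(ncol(out$data), 1024)
  expect_equal(out$fs_hz, 256)
})

test_that("downsampling refuses to upsample and is identity at equal rates", {
  x <- rnorm(100)
  expect_error(downsample(x, 512, fs_hz = 256), "upsampling")
  expect_identical(downsample(x, 256, fs_hz = 256), x)
})

test_that("broadband filter passes the band and rejects mains", {
  fs <- 256
  t <- (0:(fs * 10 - 1)) / fs
  mains <- sin(2 * pi * 50 * t)
  inband <- sin(2 * pi * 10 * t)
  keep <- (fs * 2):(fs * 8)      # avoid filter edge transients
  expect_lt(rms(broadband_filter(mains, fs_hz = fs)[keep]), 0.1 * rms(mains))
  expect_gt(rms(broadband_filter(inband, fs_hz = fs)[keep]), 0.9 * rms(inband))
  expect_equal(broadband_filter(numeric(1000), fs_hz = fs), numeric(1000))
  expect_error(broadband_filter(inband, low_hz = 0, fs_hz = fs), "band edges")
})

test_that("narrowband extraction has unit passband gain and strong stopband loss", {
  fs <- 256
  t <- (0:(fs * 8 - 1)) / fs
  keep <- (fs * 3):(fs * 5)
  s10 <- sin(2 * pi * 10 * t); s20 <- sin(2 * pi * 20 * t)
  g10 <- rms(narrowband_extract(s10, "alpha", fs_hz = fs)[keep]) / rms(s10[keep])
  g20 <- rms(narrowband_extract(s20, "alpha", fs_hz = fs)[keep]) / rms(s20[keep])
  expect_gt(g10, 0.9); expect_lt(g10, 1.1)
  expect_lt(g20, 0.03)
  expect_error(narrowband_extract(s10, c(0, 7), fs_hz = fs), "inside")
})

test_that("theta and alpha outputs of a mixture are uncorrelated", {
  fs <- 256
  set.seed(10)
  t <- (0:(fs * 10 - 1)) / fs
  x <- sin(2 * pi * 5.5 * t) + sin(2 * pi * 10 * t + 1) + rnorm(length(t), sd = 0.3)
  keep <- (fs * 2):(fs * 8)
  th <- narrowband_extract(x, "theta", fs_hz = fs)[keep]
  al <- narrowband_extract(x, "alpha", fs_hz = fs)[keep]
  expect_lt(abs(cor(th, al)), 0.05)
})

test_that("narrowband filtering is zero-phase", {
  fs <- 256
  t <- (0:(fs * 8 - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  y <- narrowband_extract(x, "alpha", fs_hz = fs)
  keep <- (fs * 3):(fs * 5)
  # no delay: filtered sinusoid stays in phase with the input
  expect_gt(cor(x[keep], y[keep]), 0.999)
})

test_that("common average referencing zeroes the retained-channel mean", {
  ep <- quiet_epochs(3, n_channels = 5)
  out <- common_average_reference(ep, excluded_channels = "ch5")
  for (tr in 1:3) {
    m <- colMeans(matrix(out$data[tr, 1:4, ], nrow = 4))
    expect_lt(max(abs(m)), 1e-10)
  }
  # already zero-mean pair is unchanged
  cont <- eeg_continuous(rbind(rep(1, 10), rep(-1, 10)), 100)
  expect_equal(common_average_reference(cont)$data, cont$data)
  single <- eeg_continuous(matrix(rnorm(10), 1), 100)
  expect_error(common_average_reference(single), "at least 2")
})

test_that("epoching cuts the half-open window and reports dropped events", {
  fs <- 256
  cont <- eeg_continuous(matrix(rnorm(2 * fs * 20), 2), fs)
  # full window support: event at 10 s
  ep <- epoch_segments(cont, c(1, 10 * fs), window_ms = c(-2000, 2000))
  expect_equal(dim(ep$data)[3], 1024)
  expect_equal(dim(ep$data)[1], 1)           # event at sample 1 dropped
  expect_equal(attr(ep, "dropped_events"), 1L)
  expect_equal(ep$t0_ms, -2000)
  expect_warning(epoch_segments(cont, c(1), window_ms = c(-2000, 2000)),
                 "no event")
})

test_that("amplitude rejection keeps plausible trials and names reasons", {
  ep <- quiet_epochs(6, n_channels = 2, amp = 25)  # 50 uV peak-to-peak
  ep$data[2, 1, 300:310] <- ep$data[2, 1, 300:310] + 300
  ep$data[5, 2, ] <- 0
  res <- reject_epochs(ep)
  expect_equal(which(res$rejected), c(2L, 5L))
  expect_equal(res$report$reason[res$report$trial == 2], "max-diff")
  expect_equal(res$report$reason[res$report$trial == 5], "flatline")
  expect_equal(dim(res$epochs$data)[1], 4)
  expect_equal(res$epochs$trial_indices, c(1L, 3L, 4L, 6L))
  expect_error(reject_epochs(ep, max_pp_window_ms = 1e6), "longer than")
})

test_that("preprocessing is deterministic and commutes with trial permutation", {
  ep <- quiet_epochs(5)
  f1 <- narrowband_extract(ep, "alpha")
  f2 <- narrowband_extract(ep, "alpha")
  expect_identical(f1, f2)
  perm <- c(3, 1, 5, 2, 4)
  epp <- ep
  epp$data <- ep$data[perm, , , drop = FALSE]
  epp$trial_indices <- ep$trial_indices[perm]
  fp <- narrowband_extract(epp, "alpha")
  expect_equal(fp$data, f1$data[perm, , , drop = FALSE])
})
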