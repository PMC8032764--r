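sine_recording <- function(freq, fs = 256, dur = 32, amp = 1e-5,
                           channels = 2) {
  t <- (0:(fs * dur - 1)) / fs
  dat <- matrix(rep(amp * sin(2 * pi * freq * t), channels),
                nrow = channels, byrow = TRUE)
  rownames(dat) <- montage_1020()[seq_len(channels)]
  eeg_recording(dat, fs)
}

test_that("the frequency grid is 41 log2-spaced frequencies from 2 to 64 Hz", {
  g <- frequency_grid()
  expect_length(g$freqs_hz, 41)
  expect_equal(g$freqs_hz[1], 2)
  expect_equal(g$freqs_hz[41], 64)
  expect_equal(diff(g$log2_freqs), rep(1 / 8, 40))
})

test_that("preprocessing notches line noise, removes DC and average-references", {
  r50 <- sine_recording(50)
  p50 <- preprocess_eeg(r50, reject_ptp_v = Inf)
  atten <- sqrt(mean(p50$data[1, ]^2)) / sqrt(mean(r50$data[1, ]^2))
  expect_lt(20 * log10(atten + 1e-300), -20)

  rdc <- sine_recording(10)
  rdc$data[1, ] <- 1e-5                      # constant channel
  pdc <- preprocess_eeg(rdc, reject_ptp_v = Inf)
  # DC component strongly attenuated (not exactly zero: finite filter)
  expect_lt(max(abs(rowMeans(pdc$data))), 0.05 * 1e-5)

  st <- fixture_eeg_study(n_subjects = 1, duration_s = 16)
  p <- preprocess_eeg(st$subjects[[1]]$recordings[[1]])
  expect_lt(max(abs(colMeans(p$data))), 1e-10)   # referencing identity
  expect_error(preprocess_eeg(eeg_recording(matrix(0, 2, 100), 256)),
               "too short")
})

test_that("large-amplitude segments are excluded by the artifact mask", {
  st <- fixture_eeg_study(n_subjects = 1, duration_s = 16)
  r <- st$subjects[[1]]$recordings[[1]]
  r$data[1, 1000:1100] <- r$data[1, 1000:1100] + 500e-6  # 500 uV transient
  p <- preprocess_eeg(r)
  expect_false(all(p$good[1000:1100]))
  expect_gt(mean(p$good), 0.5)
})

test_that("wavelet power localizes a sinusoid and scales quadratically", {
  g <- frequency_grid()
  sp <- wavelet_power(sine_recording(9.3), g)
  nearest <- g$freqs_hz[which.min(abs(g$freqs_hz - 9.3))]
  expect_equal(g$freqs_hz[which.max(channel_average(sp))], nearest)

  sp2 <- wavelet_power(sine_recording(9.3, amp = 2e-5), g)
  expect_equal(sp2$power, 4 * sp$power, tolerance = 1e-8)

  short <- eeg_recording(matrix(rnorm(2 * 256), 2), 256)
  expect_error(wavelet_power(short, g), "too short")
})

test_that("white noise yields per-log2(Hz) density proportional to f", {
  set.seed(3)
  dat <- matrix(rnorm(4 * 256 * 60, 0, 1e-5), nrow = 4)
  rownames(dat) <- montage_1020()[1:4]
  sp <- wavelet_power(eeg_recording(dat, 256), frequency_grid())
  g <- frequency_grid()
  ratio <- channel_average(sp) / g$freqs_hz
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.15)
})

test_that("spectra of a stationary signal are invariant to a 1-s shift", {
  st <- fixture_eeg_study(n_subjects = 1, duration_s = 80, seed = 4)
  r <- st$subjects[[1]]$recordings[[1]]
  fs <- r$fs_hz
  n <- 64 * fs
  r1 <- eeg_recording(r$data[, 1:n], fs)
  r2 <- eeg_recording(r$data[, (fs + 1):(n + fs)], fs)
  s1 <- channel_average(wavelet_power(r1))
  s2 <- channel_average(wavelet_power(r2))
  expect_lt(max(abs(log(s1 / s2))), 0.1)
})

test_that("total wavelet power tracks band-limited signal variance", {
  # Parseval-type check across realizations of varying amplitude
  set.seed(6)
  g <- frequency_grid()
  tot <- var_band <- numeric(20)
  for (i in 1:20) {
    tr <- eeg_study_truth(n_subjects = 1, channels = montage_1020()[1:2],
                          duration_s = 16, mixing = 0,
                          power_scale = 4e-11 * runif(1, 0.2, 5),
                          seed = 200 + i)
    x <- gen_eeg_study(tr)$subjects[[1]]$recordings[[1]]
    sp <- wavelet_power(x, g)
    tot[i] <- sum(sp$power[1, ]) * g$step_oct
    # band-limit 2-64 Hz in the frequency domain (independent route)
    n <- ncol(x$data)
    fx <- stats::fft(x$data[1, ])
    fr <- (0:(n - 1)) * x$fs_hz / n
    fr <- pmin(fr, x$fs_hz - fr)
    fx[fr < 2 | fr > 64] <- 0
    var_band[i] <- mean(Mod(stats::fft(fx, inverse = TRUE) / n)^2)
  }
  expect_gt(cor(tot, var_band), 0.99)
})

test_that("alpha peak detection returns the nearest grid frequency and flags
           boundary maxima", {
  g <- frequency_grid()
  mk_spec <- function(p) {
    structure(list(power = matrix(p, 1), freqs_hz = g$freqs_hz,
                   channels = "Cz", normalized = FALSE,
                   align_shift_oct = 0), class = "spectral_estimate")
  }
  bump <- function(f0) exp(-(g$log2_freqs - log2(f0))^2 / (2 * 0.2^2))
  pk <- detect_alpha_peak(mk_spec(1 / g$freqs_hz + bump(9.85)))
  expect_equal(pk$peak_hz, g$freqs_hz[which.min(abs(g$freqs_hz - 9.85))])
  expect_false(pk$boundary)

  pk_grid <- detect_alpha_peak(mk_spec(bump(g$freqs_hz[19])))  # 9.51 Hz
  expect_equal(pk_grid$peak_hz, g$freqs_hz[19])

  mono <- detect_alpha_peak(mk_spec(1 / g$freqs_hz))
  expect_true(mono$boundary)
  expect_equal(mono$peak_hz, g$freqs_hz[min(which(g$freqs_hz >= 7))])
})

test_that("alpha alignment shifts the spectrum in log-frequency", {
  g <- frequency_grid()
  p <- 1 / g$freqs_hz +
    exp(-(g$log2_freqs - log2(8.5))^2 / (2 * 0.2^2))
  spec <- structure(list(power = rbind(p, p), freqs_hz = g$freqs_hz,
                         channels = c("O1", "O2"), normalized = FALSE,
                         align_shift_oct = 0), class = "spectral_estimate")
  # identity when the peak is already on target
  same <- align_to_mean_alpha(spec, 9.3, 9.3)
  expect_equal(same$power, spec$power)
  # a shift of exactly one grid step is an index shift
  one <- align_to_mean_alpha(spec, 9.3 * 2^(-1 / 8), 9.3)
  expect_equal(one$power[1, 2:41], p[1:40], tolerance = 1e-10)
  expect_true(is.na(one$power[1, 1]))
  # after alignment the detected peak sits at the target
  pk <- detect_alpha_peak(align_to_mean_alpha(spec, 8.5, 9.3))
  expect_equal(pk$peak_hz,
               frequency_grid()$freqs_hz[which.min(abs(g$freqs_hz - 9.3))])
  expect_true(align_to_mean_alpha(spec, 4, 9.3)$outlier)
})

test_that("relative power normalizes per channel and is scale invariant", {
  g <- frequency_grid()
  p <- matrix(abs(rnorm(2 * 41)) + 0.1, 2)
  spec <- structure(list(power = p, freqs_hz = g$freqs_hz,
                         channels = c("O1", "O2"), normalized = FALSE,
                         align_shift_oct = 0), class = "spectral_estimate")
  rp <- relative_power(spec)
  expect_equal(rowSums(rp$power), c(1, 1))
  flat <- spec; flat$power <- matrix(3, 2, 41)
  expect_equal(relative_power(flat)$power,
               matrix(1 / 41, 2, 41), tolerance = 1e-12)
  scaled <- spec; scaled$power <- 7 * p
  expect_equal(relative_power(scaled)$power, rp$power)
  zero <- spec; zero$power <- matrix(0, 2, 41)
  expect_error(relative_power(zero), "total power")
})

test_that("power change is zero for identical conditions and rejects
           mismatched channel sets", {
  g <- frequency_grid()
  p <- matrix(abs(rnorm(2 * 41)) + 0.1, 2)
  spec <- structure(list(power = p, freqs_hz = g$freqs_hz,
                         channels = c("O1", "O2"), normalized = FALSE,
                         align_shift_oct = 0), class = "spectral_estimate")
  expect_equal(power_change(spec, spec)$power, matrix(0, 2, 41))
  other <- spec; other$channels <- c("F3", "F4")
  expect_error(power_change(spec, other), "channel")
})

test_that("the FFT spectrum variant finds a strong alpha peak", {
  tr <- eeg_study_truth(n_subjects = 1, channels = montage_1020()[1:2],
                        duration_s = 60, alpha_amp = 0.6, seed = 12)
  st <- gen_eeg_study(tr)
  fp <- fft_power_spectrum(st$subjects[[1]]$recordings[[1]])
  sel <- fp$freqs_hz >= 7 & fp$freqs_hz <= 12
  peak <- fp$freqs_hz[sel][which.max(colMeans(fp$power)[sel])]
  expect_lt(abs(peak - st$subjects[[1]]$alpha_hz), 0.75)
})
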