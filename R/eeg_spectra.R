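## Log-frequency Morlet wavelet spectra of multichannel resting EEG, with
## alpha-peak alignment and relative-power normalization.

#' Log-spaced analysis frequency grid
#'
#' 41 center frequencies `2^(1 + k/8)`, `k = 0..40` (2 to 64 Hz in steps of
#' 1/8 octave), analyzed with constant spectral quality `f / sigma_f = 5.83`
#' (half-octave smoothing).
#'
#' @param q spectral quality factor `f / sigma_f`.
#' @return list of class `freq_grid` with `freqs_hz`, `log2_freqs`,
#'   `step_oct` and `q`.
#' @export
frequency_grid <- function(q = 5.83) {
  freqs <- 2^(1 + (0:40) / 8)
  structure(list(freqs_hz = freqs, log2_freqs = log2(freqs),
                 step_oct = 1 / 8, q = q),
            class = "freq_grid")
}

#' Preprocess a raw EEG recording
#'
#' High-pass FIR filter (order `2 * fs`, zero-phase), 49-51 Hz Butterworth
#' notch (order 4, zero-phase), re-referencing to the average reference, and
#' amplitude-based artifact marking: 1-s segments in which any channel's
#' peak-to-peak amplitude exceeds `reject_ptp_v` are flagged and excluded
#' from later spectral windowing.
#'
#' @param rec an [eeg_recording()].
#' @param hp_hz high-pass cutoff (Hz).
#' @param notch_hz notch band edges (Hz).
#' @param reject_ptp_v peak-to-peak rejection threshold in volts
#'   (default 150 uV); `Inf` disables rejection.
#' @return the filtered, average-referenced recording with its `good`
#'   sample mask updated.
#' @export
preprocess_eeg <- function(rec, hp_hz = 0.5, notch_hz = c(49, 51),
                           reject_ptp_v = 150e-6) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  if (fs < 128) stop("sampling rate must be >= 128 Hz", call. = FALSE)
  n <- ncol(rec$data)
  ord <- 2 * fs
  if (n <= 3 * ord) {
    stop("recording too short for the high-pass filter (need > ",
         3 * ord, " samples)", call. = FALSE)
  }
  x <- t(rec$data)                       # time x channels
  hp <- signal::fir1(ord, hp_hz / (fs / 2), type = "high")
  bs <- signal::butter(4, notch_hz / (fs / 2), type = "stop")
  # zero-phase (forward-backward) application of both filters, realized in
  # the frequency domain as the squared magnitude response
  w <- 2 * pi * (0:(n - 1)) / n          # digital frequencies of the DFT bins
  Hhp <- Mod(stats::fft(c(unclass(hp), rep(0, n - ord - 1))))^2
  dtft <- function(coef) {
    drop(exp(-1i * outer(w, seq_along(coef) - 1)) %*% coef)
  }
  Hn <- Mod(dtft(bs$b) / dtft(bs$a))^2
  X <- stats::mvfft(x)
  x <- Re(stats::mvfft(X * (Hhp * Hn), inverse = TRUE)) / n
  x <- x - rowMeans(x)                   # average reference
  good <- rep(TRUE, n)
  if (is.finite(reject_ptp_v)) {
    seg <- floor(fs)
    n_seg <- floor(n / seg)
    for (i in seq_len(n_seg)) {
      idx <- ((i - 1L) * seg + 1L):(i * seg)
      ptp <- apply(x[idx, , drop = FALSE], 2,
                   function(v) max(v) - min(v))
      if (any(ptp > reject_ptp_v)) good[idx] <- FALSE
    }
  }
  out <- rec
  out$data <- t(x)
  rownames(out$data) <- rec$channels
  out$good <- good
  out
}

#' Morlet wavelet power spectrum on the log-frequency grid
#'
#' For each grid frequency `f`, the signal is convolved with an analytic
#' Morlet wavelet whose spectral-domain Gaussian SD is `sigma_f = f / q`
#' (temporal SD `sigma_t = 1/(2 pi sigma_f)`). Power is the mean squared
#' magnitude over successive 3/4-overlapping windows of length `6 sigma_t`
#' whose samples are all artifact-free (edge windows dropped), calibrated so
#' that the estimate is the one-sided spectral density and then scaled by
#' `f * ln 2` to per-log2(Hz) units (`V^2/log2(Hz)`): white noise thus
#' yields density proportional to `f`.
#'
#' @param rec a (preprocessed) [eeg_recording()].
#' @param grid a [frequency_grid()].
#' @return object of class `spectral_estimate`: `power` (channels x
#'   frequencies), `freqs_hz`, `channels`, `normalized = FALSE`,
#'   `align_shift_oct = 0`.
#' @export
wavelet_power <- function(rec, grid = frequency_grid()) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  n <- ncol(rec$data)
  f_min <- min(grid$freqs_hz)
  min_len <- ceiling(6 * fs * grid$q / (2 * pi * f_min))
  if (n < min_len) {
    stop("recording too short: need >= ", min_len,
         " samples (", round(min_len / fs, 1),
         " s) for the lowest analysis frequency", call. = FALSE)
  }
  x <- t(rec$data)
  X <- stats::mvfft(x)
  k <- floor(n / 2)
  freq_pos <- (0:k) * fs / n
  bad_cum <- cumsum(!rec$good)
  n_f <- length(grid$freqs_hz)
  P <- matrix(NA_real_, ncol(x), n_f,
              dimnames = list(rec$channels, NULL))
  for (i in seq_len(n_f)) {
    f <- grid$freqs_hz[i]
    sf <- f / grid$q
    st <- 1 / (2 * pi * sf)
    H <- numeric(n)
    H[1:(k + 1)] <- exp(-(freq_pos - f)^2 / (2 * sf^2))   # analytic wavelet
    W <- stats::mvfft(X * H, inverse = TRUE) / n
    half <- ceiling(3 * st * fs)
    hop <- max(1L, round(2 * half / 4))
    centers <- seq(half + 1L, n - half, by = hop)
    # a window is valid when it contains no artifact-flagged samples
    nbad <- bad_cum[pmin(centers + half, n)] -
      c(0, bad_cum)[pmax(centers - half, 1L)]
    centers <- centers[nbad == 0]
    if (!length(centers)) next
    msq <- colMeans(abs(W[centers, , drop = FALSE])^2)
    dens <- 2 * n * msq / (fs * sum(H^2))   # one-sided density, V^2/Hz
    P[, i] <- dens * f * log(2)             # per-log2(Hz) units
  }
  structure(list(power = P, freqs_hz = grid$freqs_hz,
                 channels = rec$channels, normalized = FALSE,
                 align_shift_oct = 0),
            class = "spectral_estimate")
}

#' Average several spectral estimates elementwise
#' @param specs list of `spectral_estimate`s on the same grid.
#' @export
spectra_average <- function(specs) {
  stopifnot(length(specs) >= 1L)
  out <- specs[[1L]]
  if (length(specs) > 1L) {
    arr <- vapply(specs, function(s) s$power,
                  matrix(0, nrow(out$power), ncol(out$power)))
    out$power <- apply(arr, c(1, 2), mean)
    dimnames(out$power) <- dimnames(specs[[1L]]$power)
  }
  out
}

#' Detect the individual alpha peak
#'
#' Frequency of maximal channel-averaged power within the search range
#' (default 7-12 Hz); a maximum at the range boundary is flagged as "no
#' interior peak".
#'
#' @param spec a `spectral_estimate` (eyes-closed baseline by convention).
#' @param range_hz search range.
#' @return list with `peak_hz`, `boundary` flag and `range_hz`.
#' @export
detect_alpha_peak <- function(spec, range_hz = c(7, 12)) {
  idx <- which(spec$freqs_hz >= range_hz[1] & spec$freqs_hz <= range_hz[2])
  if (!length(idx)) stop("grid does not cover the search range", call. = FALSE)
  avg <- colMeans(spec$power[, idx, drop = FALSE], na.rm = TRUE)
  i <- idx[which.max(avg)]
  list(peak_hz = spec$freqs_hz[i],
       boundary = i == idx[1L] || i == idx[length(idx)],
       range_hz = range_hz)
}

#' Shift a spectrum along log2-frequency to align its alpha peak
#'
#' The spectrum is resampled by linear interpolation in log2-frequency at an
#' offset of `delta = log2(target) - log2(peak)` octaves, so that the
#' subject's alpha peak lands on the group target (9.3 Hz by default);
#' values shifted in from beyond the grid are missing (`NA`).
#'
#' @param spec a `spectral_estimate`.
#' @param peak_hz the subject's alpha peak frequency.
#' @param target_hz alignment target.
#' @return the shifted spectrum; `align_shift_oct` records the shift and
#'   `outlier` flags `|delta| > 1` octave.
#' @export
align_to_mean_alpha <- function(spec, peak_hz, target_hz = 9.3) {
  delta <- log2(target_hz) - log2(peak_hz)
  lf <- log2(spec$freqs_hz)
  out <- spec
  if (abs(delta) > 1e-12) {
    out$power <- t(apply(spec$power, 1, function(p) {
      interp_na(lf + delta, p, lf)
    }))
    dimnames(out$power) <- dimnames(spec$power)
  }
  out$align_shift_oct <- delta
  out$outlier <- abs(delta) > 1
  out
}

#' Normalize a spectrum to unit total power per channel
#'
#' Divides each channel by its summed power over the (non-missing) grid
#' frequencies, giving relative power that sums to 1 per channel.
#'
#' @param spec a `spectral_estimate`.
#' @export
relative_power <- function(spec) {
  tot <- rowSums(spec$power, na.rm = TRUE)
  if (any(!is.finite(tot)) || any(tot <= 0)) {
    stop("total power must be > 0 in every channel", call. = FALSE)
  }
  out <- spec
  out$power <- spec$power / tot
  out$normalized <- TRUE
  out
}

#' Percent power change between matched drug and baseline spectra
#'
#' `100 * (drug - baseline) / baseline`, elementwise over channels and
#' frequencies.
#'
#' @param drug,baseline `spectral_estimate`s for the same subject/channels.
#' @return a `spectral_estimate` whose `power` holds percent changes.
#' @export
power_change <- function(drug, baseline) {
  if (!identical(drug$channels, baseline$channels)) {
    stop("drug and baseline spectra have different channel sets",
         call. = FALSE)
  }
  out <- drug
  out$power <- 100 * (drug$power - baseline$power) / baseline$power
  out$normalized <- NA
  out
}

#' Channel-averaged spectrum
#' @param spec a `spectral_estimate`.
#' @return numeric vector over grid frequencies.
#' @export
channel_average <- function(spec) {
  colMeans(spec$power, na.rm = TRUE)
}

#' FFT power spectrum (zero-padded sliding windows)
#'
#' Alternative narrowband spectrum used for alpha-peak detection: 1-s
#' windows with 3/4 overlap, zero-padded (default to 25 s) before the FFT,
#' periodograms averaged, restricted to artifact-free windows.
#'
#' @param rec a (preprocessed) [eeg_recording()].
#' @param window_s window length in seconds.
#' @param overlap fractional window overlap.
#' @param pad_s zero-padded length in seconds.
#' @return list with `freqs_hz` and `power` (channels x frequencies).
#' @export
fft_power_spectrum <- function(rec, window_s = 1, overlap = 0.75,
                               pad_s = 25) {
  fs <- rec$fs_hz
  L <- round(window_s * fs)
  Np <- round(pad_s * fs)
  hop <- max(1L, round(L * (1 - overlap)))
  n <- ncol(rec$data)
  starts <- seq(1L, n - L + 1L, by = hop)
  starts <- starts[vapply(starts,
                          function(s) all(rec$good[s:(s + L - 1L)]), TRUE)]
  if (!length(starts)) stop("no artifact-free windows", call. = FALSE)
  k <- floor(Np / 2)
  acc <- matrix(0, nrow(rec$data), k + 1L)
  for (s in starts) {
    seg <- matrix(0, Np, nrow(rec$data))
    seg[1:L, ] <- t(rec$data[, s:(s + L - 1L), drop = FALSE])
    X <- stats::mvfft(seg)
    acc <- acc + t(abs(X[1:(k + 1L), , drop = FALSE])^2)
  }
  list(freqs_hz = (0:k) * fs / Np,
       power = acc / length(starts) * 2 / (fs * L))
}

#' Run the full EEG spectral pipeline on a synthetic study
#'
#' Per subject: preprocess each recording, compute wavelet spectra, average
#' recordings within condition, detect the baseline alpha peak, align both
#' conditions to the group target, normalize to relative power, and compute
#' the drug-versus-baseline percent change.
#'
#' @param study an [gen_eeg_study()] result.
#' @param grid a [frequency_grid()].
#' @param align_target_hz alpha alignment target in Hz; `NULL` disables
#'   alignment.
#' @param preprocess whether to run [preprocess_eeg()] first.
#' @return list with `change` (subjects x frequencies percent change,
#'   channel-averaged), `change_channels` (subjects x channels x
#'   frequencies), `alpha_hz` (detected peaks), `freqs_hz`.
#' @export
eeg_change_spectra <- function(study, grid = frequency_grid(),
                               align_target_hz = 9.3, preprocess = TRUE) {
  stopifnot(inherits(study, "eeg_study"))
  n_sub <- length(study$subjects)
  n_f <- length(grid$freqs_hz)
  n_ch <- length(study$channels)
  change <- matrix(NA_real_, n_sub, n_f)
  change_ch <- array(NA_real_, c(n_sub, n_ch, n_f))
  alpha <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    sub <- study$subjects[[s]]
    by_cond <- list()
    for (cond in c("baseline", "drug")) {
      recs <- Filter(function(r) r$condition == cond, sub$recordings)
      specs <- lapply(recs, function(r) {
        if (preprocess) r <- preprocess_eeg(r)
        wavelet_power(r, grid)
      })
      by_cond[[cond]] <- spectra_average(specs)
    }
    pk <- detect_alpha_peak(by_cond$baseline)
    alpha[s] <- pk$peak_hz
    if (!is.null(align_target_hz)) {
      by_cond <- lapply(by_cond, align_to_mean_alpha, peak_hz = pk$peak_hz,
                        target_hz = align_target_hz)
    }
    by_cond <- lapply(by_cond, relative_power)
    ch <- power_change(by_cond$drug, by_cond$baseline)
    change[s, ] <- channel_average(ch)
    change_ch[s, , ] <- ch$power
  }
  list(change = change, change_channels = change_ch, alpha_hz = alpha,
       freqs_hz = grid$freqs_hz)
}
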