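# Shared fixtures, built in code.

# log-spaced concentration grid (nM)
conc_grid <- function(n = 12, lo = 1, hi = 1000) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

# frame-averaged analytic reference curve on the standard schedule
fixture_reference <- function() {
  tr <- pet_study_truth(noise_sd = 0)
  neuropkpd:::pet_reference_frames(tr)
}

# small EEG study; kept short for test speed
fixture_eeg_study <- function(n_subjects = 2, channels = 3, duration_s = 48,
                              effects = list(), seed = 11) {
  gen_eeg_study(eeg_study_truth(
    n_subjects = n_subjects,
    channels = montage_1020()[seq_len(channels)],
    duration_s = duration_s, effects = effects, seed = seed))
}

# synthetic per-subject relative-power-change spectra: iid Gaussian noise
# around a mean profile, on the standard 41-point grid
fixture_change_spectra <- function(n_subjects, profile = rep(0, 41),
                                   sd = 5) {
  matrix(stats::rnorm(n_subjects * length(profile), 0, sd),
         n_subjects, byrow = TRUE, ncol = length(profile)) +
    matrix(profile, n_subjects, length(profile), byrow = TRUE)
}
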