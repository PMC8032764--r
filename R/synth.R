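## Synthetic-data generators with known ground truth for every pipeline
## stage: concentration-response tables, autoradiography cohorts, SRTM PET
## scans and multichannel resting EEG.

#' Generate a replicated concentration-response table
#'
#' Responses follow the four-parameter Hill curve
#' `A + (B - A)/(1 + (C/x)^D)` plus additive Gaussian noise.
#'
#' @param truth list with `A`, `B`, `C` (midpoint, nM > 0) and `D` (slope).
#' @param concentrations concentrations in nM (> 0).
#' @param replicates replicates per concentration (>= 1).
#' @param noise_sd additive noise SD in response units.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return data.frame with `conc_nM`, `response`, `replicate`; ground truth
#'   attached as attribute `"truth"`.
#' @export
gen_conc_response <- function(truth, concentrations, replicates = 1,
                              noise_sd = 0, seed = NULL) {
  stop_if_not_positive(concentrations, "concentrations")
  stopifnot(replicates >= 1)
  x <- rep(concentrations, each = replicates)
  mu <- hill_response(x, truth$A, truth$B, truth$C, truth$D)
  y <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  out <- data.frame(conc_nM = x, response = y,
                    replicate = rep(seq_len(replicates),
                                    times = length(concentrations)))
  attr(out, "truth") <- truth
  out
}

#' Ground truth for a rat ex vivo occupancy cohort
#'
#' Defaults mirror a four-dose intravenous-radioligand occupancy study:
#' doses 3/10/30/100 mg/kg, lognormal plasma levels proportional to dose
#' (12.7 ng/mL per mg/kg, CV 30%), occupancy EC50 544 ng/mL total plasma,
#' and regional target-specific densities over a non-displaceable plateau
#' (hippocampus 304 fmol/mg specific over a 100 fmol/mg plateau).
#'
#' @param doses_mg_kg dose groups.
#' @param plasma_per_dose median plasma (ng/mL) per unit dose.
#' @param plasma_cv lognormal coefficient of variation of plasma levels.
#' @param ec50_ng_ml occupancy EC50 in total-plasma units.
#' @param regions data.frame with `region`, `alpha5_fmol_mg` (drug-displaceable
#'   specific density) and `plateau_fmol_mg` (non-displaceable signal).
#' @param noise_sd measurement noise SD (fmol/mg).
#' @param n_per_group animals per treatment group (>= 1).
#' @param seed RNG seed.
#' @return list of class `occupancy_truth`.
#' @export
occupancy_cohort_truth <- function(doses_mg_kg = c(3, 10, 30, 100),
                                   plasma_per_dose = 12.7,
                                   plasma_cv = 0.3,
                                   ec50_ng_ml = 544,
                                   regions = data.frame(
                                     region = c("hippocampus", "frontal_cortex",
                                                "striatum", "cerebellum"),
                                     alpha5_fmol_mg = c(304, 192, 25, 38),
                                     plateau_fmol_mg = c(100, 80, 60, 50)),
                                   noise_sd = 18,
                                   n_per_group = 4,
                                   seed = NULL) {
  stopifnot(n_per_group >= 1, ec50_ng_ml > 0,
            all(regions$alpha5_fmol_mg >= 0),
            all(regions$plateau_fmol_mg >= 0))
  structure(list(doses_mg_kg = doses_mg_kg, plasma_per_dose = plasma_per_dose,
                 plasma_cv = plasma_cv, ec50_ng_ml = ec50_ng_ml,
                 regions = regions, noise_sd = noise_sd,
                 n_per_group = n_per_group, seed = seed),
            class = "occupancy_truth")
}

#' Generate an autoradiography occupancy cohort
#'
#' Emits vehicle, blocker (full pharmacological block) and dosed animals.
#' The blocker group's signal is the non-displaceable plateau; vehicle adds
#' the full target-specific density; dosed animals add the density scaled by
#' the unoccupied fraction `1 - C/(EC50 + C)` at their simulated plasma
#' level `C`. All signals receive additive Gaussian noise.
#'
#' @param truth an [occupancy_cohort_truth()].
#' @return data.frame with `animal_id`, `treatment` (`"vehicle"`,
#'   `"blocker"`, `"drug"`), `dose_mg_kg`, `region`, `signal_fmol_mg`,
#'   `plasma_ng_ml`; ground truth attached as attribute `"truth"`.
#' @export
gen_occupancy_cohort <- function(truth) {
  stopifnot(inherits(truth, "occupancy_truth"))
  with_seed(truth$seed, {
    groups <- c("vehicle", "blocker", paste0("dose", truth$doses_mg_kg))
    rows <- list()
    animal <- 0L
    sdlog <- sqrt(log(1 + truth$plasma_cv^2))
    for (g in seq_along(groups)) {
      is_dose <- g > 2L
      dose <- if (is_dose) truth$doses_mg_kg[g - 2L] else NA_real_
      for (i in seq_len(truth$n_per_group)) {
        animal <- animal + 1L
        plasma <- if (is_dose) {
          stats::rlnorm(1, meanlog = log(truth$plasma_per_dose * dose),
                        sdlog = sdlog)
        } else {
          NA_real_
        }
        unocc <- if (is_dose) {
          1 - plasma / (truth$ec50_ng_ml + plasma)
        } else if (groups[g] == "vehicle") 1 else 0
        mu <- truth$regions$plateau_fmol_mg +
          truth$regions$alpha5_fmol_mg * unocc
        sig <- mu + stats::rnorm(nrow(truth$regions), 0, truth$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("A%03d", animal),
          treatment = if (is_dose) "drug" else groups[g],
          dose_mg_kg = dose,
          region = truth$regions$region,
          signal_fmol_mg = sig,
          plasma_ng_ml = plasma,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Ground truth for a paired baseline / post-dose SRTM PET study
#'
#' The reference-region curve is a difference of exponentials (bolus-like
#' rise and washout); target regions are defined by SRTM parameters, and the
#' post-dose scan scales each region's BP_ND by `1 - occupancy`. Frame noise
#' is Gaussian with SD scaling as `1/sqrt(frame duration)` (count-statistics
#' proxy), parameterized by the SD at a 60-s frame.
#'
#' @param frames frame schedule; default [pet_frame_schedule()].
#' @param ref_amp,ref_k_slow,ref_k_fast reference curve
#'   `amp * (exp(-k_slow t) - exp(-k_fast t))`, t in minutes, kBq/mL.
#' @param regions data.frame with `region`, `R1`, `k2`, `BP_ND`.
#' @param occupancy occupancy fraction applied in the post-dose scan, in
#'   `[0, 1]`.
#' @param ia_mbq injected activity (MBq); `bw_kg` body weight (kg).
#' @param noise_sd frame noise SD (kBq/mL) at a 60-s frame; 0 disables noise.
#' @param seed RNG seed.
#' @return list of class `pet_truth`.
#' @export
pet_study_truth <- function(frames = pet_frame_schedule(),
                            ref_amp = 45, ref_k_slow = 0.12, ref_k_fast = 4,
                            regions = data.frame(
                              region = c("hippocampus", "frontal_cortex",
                                         "striatum"),
                              R1 = c(1.05, 1.00, 0.95),
                              k2 = c(0.20, 0.20, 0.18),
                              BP_ND = c(2.0, 1.2, 0.6)),
                            occupancy = 0.94,
                            ia_mbq = 290, bw_kg = 75,
                            noise_sd = 0, seed = NULL) {
  validate_frames(frames)
  if (occupancy < 0 || occupancy > 1) {
    stop("`occupancy` must be in [0, 1]", call. = FALSE)
  }
  stopifnot(all(regions$BP_ND >= 0), all(regions$k2 > 0))
  structure(list(frames = frames, ref_amp = ref_amp,
                 ref_k_slow = ref_k_slow, ref_k_fast = ref_k_fast,
                 regions = regions, occupancy = occupancy,
                 ia_mbq = ia_mbq, bw_kg = bw_kg,
                 noise_sd = noise_sd, seed = seed),
            class = "pet_truth")
}

## Frame-averaged analytic reference curve (t in minutes).
pet_reference_frames <- function(truth) {
  f <- function(t) truth$ref_amp * (exp(-truth$ref_k_slow * t) -
                                      exp(-truth$ref_k_fast * t))
  vapply(seq_len(nrow(truth$frames)), function(i) {
    a <- truth$frames$start_s[i] / 60
    b <- a + truth$frames$dur_s[i] / 60
    stats::integrate(f, a, b, rel.tol = 1e-10)$value / (b - a)
  }, 0)
}

#' Generate a paired baseline / post-dose PET study
#'
#' @param truth a [pet_study_truth()].
#' @return list with `frames`, `meta` (`ia_mbq`, `bw_kg`, reference label)
#'   and `scans`: for `baseline` and `postdose`, the framed reference TAC and
#'   one framed target TAC per region (kBq/mL). Ground truth in `$truth`.
#' @export
gen_pet_study <- function(truth) {
  stopifnot(inherits(truth, "pet_truth"))
  ref <- pet_reference_frames(truth)
  noise <- function(n) {
    if (truth$noise_sd == 0) return(numeric(n))
    stats::rnorm(n, 0, truth$noise_sd * sqrt(60 / truth$frames$dur_s))
  }
  with_seed(truth$seed, {
    scans <- list()
    for (scan in c("baseline", "postdose")) {
      occ <- if (scan == "postdose") truth$occupancy else 0
      targets <- list()
      for (i in seq_len(nrow(truth$regions))) {
        r <- truth$regions[i, ]
        tac <- srtm_forward(truth$frames, ref, r$R1, r$k2,
                            r$BP_ND * (1 - occ))
        targets[[r$region]] <- tac + noise(length(tac))
      }
      scans[[scan]] <- list(reference = ref + noise(length(ref)),
                            targets = targets)
    }
    list(frames = truth$frames,
         meta = list(ia_mbq = truth$ia_mbq, bw_kg = truth$bw_kg,
                     reference_region = "cerebellum"),
         scans = scans, truth = truth)
  })
}

#' Standard 19-channel 10/20 montage labels
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz", "C4",
    "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

#' One band-limited multiplicative drug effect for the EEG generator
#'
#' @param center_hz center frequency of the effect (Hz).
#' @param width_oct Gaussian SD of the effect profile in log2-frequency
#'   (octaves).
#' @param change fractional power change at the center (e.g. `0.19` for
#'   +19%, `-0.19` for -19%).
#' @param weights per-channel topography weights (recycled; default uniform).
#' @export
eeg_effect <- function(center_hz, width_oct = 0.5, change = 0.19,
                       weights = 1) {
  stopifnot(center_hz > 0, width_oct > 0, all(is.finite(weights)))
  list(center_hz = center_hz, width_oct = width_oct, change = change,
       weights = weights)
}

#' Ground truth for a synthetic resting-EEG study
#'
#' Each subject's baseline power spectral density is
#' `scale * (f^-gamma + amp * exp(-(log2 f - log2 p)^2 / (2 * 0.2^2)))`
#' with a subject-specific alpha peak `p ~ N(9.3, 0.87^2)` Hz. Under drug
#' the density is multiplied by the product of the effect profiles
#' (Gaussian in log2-frequency). Recordings are realized by shaping the
#' spectrum of white noise; a shared latent source (channel-mean density,
#' mixing weight `mixing`) induces cross-channel correlation.
#'
#' @param n_subjects number of subjects.
#' @param channels channel labels; default the 19-channel 10/20 montage.
#' @param fs_hz sampling rate (must exceed twice the 64 Hz analysis limit).
#' @param duration_s seconds of data per recording.
#' @param n_recordings recordings per condition per subject.
#' @param gamma background spectral exponent (`1/f^gamma`).
#' @param alpha_mean_hz,alpha_sd_hz distribution of subject alpha peaks.
#' @param alpha_amp alpha bump coefficient (density units relative to the
#'   `f^-gamma` term); per-subject lognormal variation with 30% CV.
#' @param alpha_width_oct Gaussian SD of the alpha bump (octaves).
#' @param effects list of [eeg_effect()]s applied under drug.
#' @param mixing shared-source mixing coefficient in `[0, 1)`.
#' @param power_scale overall density scale (V^2/Hz); default gives a
#'   realistic ~15 uV RMS.
#' @param seed RNG seed.
#' @return list of class `eeg_truth`.
#' @export
eeg_study_truth <- function(n_subjects = 12, channels = montage_1020(),
                            fs_hz = 256, duration_s = 220,
                            n_recordings = 1,
                            gamma = 1, alpha_mean_hz = 9.3,
                            alpha_sd_hz = 0.87, alpha_amp = 0.25,
                            alpha_width_oct = 0.2,
                            effects = list(), mixing = 0.3,
                            power_scale = 4e-11, seed = NULL) {
  if (fs_hz <= 2 * 64) {
    stop("sampling rate must exceed twice the 64 Hz analysis limit",
         call. = FALSE)
  }
  for (e in effects) {
    if (e$center_hz >= fs_hz / 2) {
      stop("effect profile extends above the Nyquist frequency",
           call. = FALSE)
    }
  }
  structure(list(n_subjects = n_subjects, channels = channels,
                 fs_hz = fs_hz, duration_s = duration_s,
                 n_recordings = n_recordings, gamma = gamma,
                 alpha_mean_hz = alpha_mean_hz, alpha_sd_hz = alpha_sd_hz,
                 alpha_amp = alpha_amp, alpha_width_oct = alpha_width_oct,
                 effects = effects, mixing = mixing,
                 power_scale = power_scale, seed = seed),
            class = "eeg_truth")
}

#' A single multichannel EEG recording
#'
#' @param data channels x time matrix (volts).
#' @param fs_hz sampling rate.
#' @param channels channel labels.
#' @param subject,condition identifiers.
#' @export
eeg_recording <- function(data, fs_hz, channels = rownames(data),
                          subject = NA_character_,
                          condition = NA_character_) {
  stopifnot(is.matrix(data), nrow(data) >= 2L)
  structure(list(data = data, fs_hz = fs_hz, channels = channels,
                 subject = subject, condition = condition,
                 good = rep(TRUE, ncol(data))),
            class = "eeg_recording")
}

## Per-channel target one-sided PSD (V^2/Hz) on a frequency vector.
eeg_psd <- function(freq_hz, truth, alpha_hz, alpha_amp, drug = FALSE) {
  f <- pmax(freq_hz, 0.5)              # clamp the 1/f divergence below 0.5 Hz
  base <- f^(-truth$gamma) +
    alpha_amp * exp(-(log2(f) - log2(alpha_hz))^2 /
                      (2 * truth$alpha_width_oct^2))
  n_ch <- length(truth$channels)
  P <- matrix(base, nrow = length(freq_hz), ncol = n_ch)
  if (drug) {
    for (e in truth$effects) {
      w <- rep_len(e$weights, n_ch)
      prof <- exp(-(log2(f) - log2(e$center_hz))^2 / (2 * e$width_oct^2))
      P <- P * (1 + outer(prof * e$change, w))
    }
  }
  P[freq_hz == 0, ] <- 0
  P * truth$power_scale
}

## Realize one recording by spectrum-shaping white noise (frequency-domain
## amplitude sqrt(P * fs / 2), Hermitian-symmetric so the output is real).
shape_noise <- function(n, fs, P) {
  k <- floor(n / 2)
  # mirror positive-frequency rows onto the negative frequencies so the
  # filter is Hermitian-symmetric and the output real
  idx <- c(1:(k + 1), if (n %% 2 == 0) k:2 else (k + 1):2)
  H <- sqrt(P[idx, , drop = FALSE] * fs / 2)
  w <- matrix(stats::rnorm(n * ncol(P)), n, ncol(P))
  W <- stats::mvfft(w)
  Re(stats::mvfft(W * H, inverse = TRUE)) / n
}

#' Generate a synthetic resting-EEG study
#'
#' @param truth an [eeg_study_truth()].
#' @return list of class `eeg_study`: `subjects` (each with `id`,
#'   `alpha_hz`, and `recordings`, a list of [eeg_recording()]s for
#'   conditions `"baseline"` and `"drug"`), plus `fs_hz`, `channels` and the
#'   generating `truth`.
#' @export
gen_eeg_study <- function(truth) {
  stopifnot(inherits(truth, "eeg_truth"))
  n <- round(truth$duration_s * truth$fs_hz)
  k <- floor(n / 2)
  freq_pos <- (0:k) * truth$fs_hz / n
  n_ch <- length(truth$channels)
  m <- truth$mixing
  with_seed(truth$seed, {
    subjects <- vector("list", truth$n_subjects)
    for (s in seq_len(truth$n_subjects)) {
      alpha_hz <- min(11.5, max(7.5, stats::rnorm(1, truth$alpha_mean_hz,
                                                  truth$alpha_sd_hz)))
      amp <- truth$alpha_amp * stats::rlnorm(1, -0.3^2 / 2, 0.3)
      recs <- list()
      for (cond in c("baseline", "drug")) {
        P <- eeg_psd(freq_pos, truth, alpha_hz, amp, drug = cond == "drug")
        Pfull <- cbind(P, rowMeans(P))   # last column: shared latent source
        for (r in seq_len(truth$n_recordings)) {
          x <- shape_noise(n, truth$fs_hz, Pfull)
          dat <- t(sqrt(1 - m) * x[, seq_len(n_ch), drop = FALSE] +
                     sqrt(m) * x[, n_ch + 1L])
          rownames(dat) <- truth$channels
          recs[[length(recs) + 1L]] <- eeg_recording(
            dat, truth$fs_hz, truth$channels,
            subject = sprintf("S%02d", s), condition = cond)
        }
      }
      subjects[[s]] <- list(id = sprintf("S%02d", s), alpha_hz = alpha_hz,
                            alpha_amp = amp, recordings = recs)
    }
    structure(list(subjects = subjects, fs_hz = truth$fs_hz,
                   channels = truth$channels, truth = truth),
              class = "eeg_study")
  })
}
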