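test_that("concentration-response generator hits the Hill curve exactly
           without noise and validates its inputs", {
  truth <- list(A = 0, B = 100, C = 10, D = 1)
  at_mid <- gen_conc_response(truth, 10, 1, 0)
  expect_equal(at_mid$response, 50)                      # midpoint
  at_inf <- gen_conc_response(truth, 1e9, 1, 0)
  expect_equal(at_inf$response, 100, tolerance = 1e-6)   # ceiling
  expect_error(gen_conc_response(truth, c(-1, 10), 1, 0), "concentrations")

  tab <- gen_conc_response(truth, conc_grid(6), 3, 0.5, seed = 5)
  expect_equal(nrow(tab), 18)
  expect_identical(tab, gen_conc_response(truth, conc_grid(6), 3, 0.5,
                                          seed = 5))    # determinism
})

test_that("generated curves round-trip through the Hill fit", {
  tab <- gen_conc_response(list(A = 0, B = -42, C = 8, D = 0.9),
                           conc_grid(12), 1, 0)
  fit <- fit_hill(tab$conc_nM, tab$response)
  expect_lt(abs(fit$estimates[["C"]] - 8) / 8, 1e-6)
  expect_lt(abs(fit$estimates[["D"]] - 0.9) / 0.9, 1e-6)
})

test_that("occupancy cohort generator composes plateau, target density and
           occupancy as specified", {
  # plasma fixed at the EC50: dose 1 with unit-dose median equal to EC50
  truth <- occupancy_cohort_truth(
    doses_mg_kg = 1, plasma_per_dose = 544, plasma_cv = 1e-12,
    ec50_ng_ml = 544, noise_sd = 0, n_per_group = 2, seed = 1,
    regions = data.frame(region = "hippocampus", alpha5_fmol_mg = 304,
                         plateau_fmol_mg = 100))
  cohort <- gen_occupancy_cohort(truth)
  blk <- cohort$signal_fmol_mg[cohort$treatment == "blocker"]
  veh <- cohort$signal_fmol_mg[cohort$treatment == "vehicle"]
  drg <- cohort$signal_fmol_mg[cohort$treatment == "drug"]
  expect_equal(blk, rep(100, 2))          # plateau only
  expect_equal(veh, rep(404, 2))          # plateau + full density
  expect_equal(drg, rep(100 + 304 / 2, 2), tolerance = 1e-6)  # half occupancy
  expect_error(occupancy_cohort_truth(n_per_group = 0), "n_per_group")
  expect_identical(gen_occupancy_cohort(truth), gen_occupancy_cohort(truth))
})

test_that("PET study generator respects occupancy and the SRTM degeneracies", {
  t0 <- pet_study_truth(occupancy = 0, noise_sd = 0, seed = 2)
  s0 <- gen_pet_study(t0)
  expect_equal(s0$scans$baseline$targets$hippocampus,
               s0$scans$postdose$targets$hippocampus)   # occupancy 0

  t1 <- pet_study_truth(regions = data.frame(region = "r", R1 = 1,
                                             k2 = 0.2, BP_ND = 0),
                        occupancy = 0, noise_sd = 0)
  s1 <- gen_pet_study(t1)
  expect_equal(s1$scans$baseline$targets$r, s1$scans$baseline$reference,
               tolerance = 1e-12)                       # R1=1, BP=0
  expect_error(pet_study_truth(occupancy = 1.2), "occupancy")
})

test_that("generated scans round-trip to the generating occupancy", {
  st <- gen_pet_study(pet_study_truth(occupancy = 0.94, noise_sd = 0))
  for (rg in c("hippocampus", "frontal_cortex")) {
    b <- srtm_fit_basis(st$scans$baseline$targets[[rg]], st$frames,
                        st$scans$baseline$reference)
    p <- srtm_fit_basis(st$scans$postdose$targets[[rg]], st$frames,
                        st$scans$postdose$reference)
    expect_equal(occupancy_from_bp(b$BP_ND, p$BP_ND), 0.94,
                 tolerance = 0.01)
  }
})

test_that("EEG generator is deterministic under a fixed seed and rejects
           effects beyond Nyquist", {
  s1 <- fixture_eeg_study(n_subjects = 1, duration_s = 16, seed = 33)
  s2 <- fixture_eeg_study(n_subjects = 1, duration_s = 16, seed = 33)
  expect_identical(s1$subjects[[1]]$recordings[[1]]$data,
                   s2$subjects[[1]]$recordings[[1]]$data)
  expect_error(eeg_study_truth(effects = list(eeg_effect(200))), "Nyquist")
  expect_error(eeg_study_truth(fs_hz = 100), "sampling rate")
})

test_that("the realized EEG spectrum converges to the specified density
           within 5% in every half-octave band", {
  # raw periodogram band averages (independent of the wavelet estimator)
  ratios <- NULL
  n_real <- 6
  for (i in seq_len(n_real)) {
    tr <- eeg_study_truth(n_subjects = 1, channels = montage_1020()[1:2],
                          duration_s = 128, mixing = 0, seed = 100 + i)
    st <- gen_eeg_study(tr)
    sub <- st$subjects[[1]]
    x <- sub$recordings[[1]]$data
    n <- ncol(x)
    freq <- (0:(n - 1)) * tr$fs_hz / n
    theo <- neuropkpd:::eeg_psd(freq, tr, sub$alpha_hz, sub$alpha_amp)[, 1]
    band <- cut(log2(pmax(freq, 1e-9)), seq(1, 6, by = 0.5),
                include.lowest = TRUE)
    per_band <- function(v) tapply(v, band, mean)
    for (ch in 1:2) {
      pg <- Mod(stats::fft(x[ch, ]))^2 / (n * tr$fs_hz) * 2
      ratios <- rbind(ratios, per_band(pg) / per_band(theo))
    }
  }
  expect_true(all(abs(colMeans(ratios) - 1) < 0.05))
})

test_that("without a drug effect the drug and baseline recordings are
           exchangeable: the grand-mean change is near zero", {
  st <- fixture_eeg_study(n_subjects = 6, channels = 2, duration_s = 64,
                          seed = 77)
  ch <- eeg_change_spectra(st, align_target_hz = NULL, preprocess = FALSE)
  expect_lt(abs(mean(ch$change)), 3)
})
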