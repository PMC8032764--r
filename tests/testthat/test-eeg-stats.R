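grid_freqs <- frequency_grid()$freqs_hz
grid_l2 <- log2(grid_freqs)

# Gaussian bump profile in log2-frequency, used to synthesize effects
bump_profile <- function(center_hz, height, width_oct = 0.4) {
  height * exp(-(grid_l2 - log2(center_hz))^2 / (2 * width_oct^2))
}

test_that("identical conditions produce no clusters", {
  set.seed(1)
  a <- fixture_change_spectra(8)
  ct <- cluster_randomization_test(a, a, grid_freqs, n_perm = 500, seed = 2)
  expect_equal(nrow(ct$clusters), 0)
  expect_true(all(ct$t == 0, na.rm = TRUE))
})

test_that("the paired test is invariant to subject-specific offsets added
           to both conditions", {
  set.seed(10)
  a <- fixture_change_spectra(10, bump_profile(8, 6))
  b <- fixture_change_spectra(10)
  off <- matrix(rnorm(10, 0, 50), 10, 41)
  c1 <- cluster_randomization_test(a, b, grid_freqs, n_perm = 1000, seed = 3)
  c2 <- cluster_randomization_test(a + off, b + off, grid_freqs,
                                   n_perm = 1000, seed = 3)
  expect_equal(c1$clusters, c2$clusters)
  expect_equal(c1$t, c2$t)
})

test_that("sign patterns are enumerated exhaustively for small samples and
           Monte-Carlo p-values stabilize with many permutations", {
  set.seed(4)
  a <- fixture_change_spectra(6, bump_profile(8, 8))
  b <- fixture_change_spectra(6)
  ct <- cluster_randomization_test(a, b, grid_freqs, n_perm = 1000)
  expect_true(ct$exhaustive)
  expect_equal(ct$n_perm_used, 64)

  a12 <- fixture_change_spectra(12, bump_profile(8, 6))
  b12 <- fixture_change_spectra(12)
  ps <- vapply(1:5, function(s) {
    ct <- cluster_randomization_test(a12, b12, grid_freqs,
                                     n_perm = 10000, seed = s)
    if (nrow(ct$clusters)) min(ct$clusters$p) else 1
  }, 0)
  expect_lt(sd(ps), 0.01)
})

test_that("missing frequencies (e.g. after alignment) are excluded from
           cluster formation without breaking the test", {
  set.seed(12)
  a <- fixture_change_spectra(8, bump_profile(8, 8))
  b <- fixture_change_spectra(8)
  a[1, 1:2] <- NA
  ct <- cluster_randomization_test(a, b, grid_freqs, n_perm = 500, seed = 1)
  expect_true(all(is.na(ct$t[1:2])))
  expect_true(nrow(ct$clusters) >= 1)
})

test_that("an injected broad positive effect is detected as a positive
           cluster overlapping its band in at least 90% of repetitions", {
  hits <- 0
  for (i in 1:100) {
    set.seed(1000 + i)
    a <- fixture_change_spectra(12, bump_profile(7.3, 20, 0.3), sd = 8)
    b <- fixture_change_spectra(12, sd = 8)
    ct <- cluster_randomization_test(a, b, grid_freqs, n_perm = 1000,
                                     seed = i)
    cl <- ct$clusters
    ok <- nrow(cl) && any(cl$p < 0.05 & cl$sign > 0 &
                            cl$start_hz <= 9 & cl$end_hz >= 6)
    hits <- hits + ok
  }
  expect_gte(hits, 90)
})

test_that("jackknife peak estimation: identical subjects give zero SEM and
           linear statistics reproduce the full-sample value", {
  prof <- bump_profile(18.4, 10)
  effect <- matrix(prof, 8, 41, byrow = TRUE)
  pe <- jackknife_peak(effect, grid_freqs, c(12, 48))
  expect_equal(pe$sem_hz, 0)
  expect_equal(pe$peak_hz, pe$theta_full)
  expect_lt(abs(pe$peak_hz - 18.4), 0.5)

  # jackknife identity for a statistic linear in subjects
  set.seed(20)
  x <- matrix(rnorm(8 * 41), 8)
  pv <- jackknife_pseudo_values(x, function(m) mean(m[, 17]))
  expect_equal(mean(pv), mean(x[, 17]), tolerance = 1e-12)

  flat <- jackknife_peak(matrix(1, 5, 41), grid_freqs, c(12, 48))
  expect_true(flat$flat)
})

test_that("peak frequencies of well-separated effects are distinguished in
           at least 90% of repetitions", {
  hits <- 0
  for (i in 1:100) {
    set.seed(3000 + i)
    e1 <- fixture_change_spectra(12, bump_profile(18.4, 25, 0.3), sd = 6)
    e2 <- fixture_change_spectra(12, bump_profile(34.9, 25, 0.3), sd = 6)
    p1 <- jackknife_peak(e1, grid_freqs, c(12, 48))
    p2 <- jackknife_peak(e2, grid_freqs, c(12, 48))
    p <- compare_peaks(p1, p2)$p.value
    hits <- hits + (is.finite(p) && p < 0.05)
  }
  expect_gte(hits, 90)
})

test_that("topography similarity: shared pattern gives a null result,
           orthogonal patterns are detected, and the statistic is
           exchangeable in subject order", {
  n_ch <- 19
  common <- sin(seq(0, 3 * pi, length.out = n_ch))
  set.seed(30)
  t1 <- matrix(common, 10, n_ch, byrow = TRUE) + rnorm(10 * n_ch, 0, 0.3)
  t2 <- matrix(common, 10, n_ch, byrow = TRUE) + rnorm(10 * n_ch, 0, 0.3)
  res <- topography_similarity_test(t1, t2, n_perm = 1000, seed = 5)
  expect_lt(abs(res$statistic), 0.1)
  expect_gt(res$p, 0.05)

  # permuting subject rows changes nothing
  res2 <- topography_similarity_test(t1[10:1, ], t2, n_perm = 1000, seed = 5)
  expect_equal(res2$r_within, res$r_within)
  expect_equal(res2$r_between, res$r_between)

  # orthogonal group patterns with moderate subject noise
  pat1 <- sin(seq(0, 2 * pi, length.out = n_ch))
  pat2 <- cos(seq(0, 2 * pi, length.out = n_ch))
  hits <- 0
  for (i in 1:100) {
    set.seed(4000 + i)
    g1 <- matrix(pat1, 12, n_ch, byrow = TRUE) + rnorm(12 * n_ch, 0, 0.6)
    g2 <- matrix(pat2, 12, n_ch, byrow = TRUE) + rnorm(12 * n_ch, 0, 0.6)
    res <- topography_similarity_test(g1, g2, n_perm = 500, seed = i)
    hits <- hits + (res$p < 0.01)
  }
  expect_gte(hits, 90)
})

test_that("the topography test keeps its nominal type-I error under label
           exchangeability", {
  rejections <- 0
  n_data <- 500
  for (i in seq_len(n_data)) {
    set.seed(5000 + i)
    pool <- matrix(rnorm(12 * 19), 12)
    res <- topography_similarity_test(pool[1:6, ], pool[7:12, ],
                                      n_perm = 300, seed = i)
    rejections <- rejections + (res$p < 0.05)
  }
  rate <- rejections / n_data
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})
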