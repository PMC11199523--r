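test_that("spectral noise is deterministic, standardized, and obeys the slope", {
  x1 <- spectral_noise(4096, 300, slope = 1, seed = 5)
  x2 <- spectral_noise(4096, 300, slope = 1, seed = 5)
  expect_identical(x1, x2)
  expect_equal(mean(x1), 0, tolerance = 1e-12)
  expect_equal(sd(x1), 1, tolerance = 1e-12)
  expect_error(spectral_noise(8, 300), ">= 16")
  expect_error(spectral_noise(1024, -1), "positive")

  # flat spectrum at slope 0; 1/f at slope 1 (averaged over seeds)
  sl0 <- mean(vapply(1:20, function(i) {
    fit_spectral_slope(spectral_noise(4096, 300, slope = 0, seed = i), 300)
  }, numeric(1)))
  expect_lt(abs(sl0), 0.1)
  sl1 <- mean(vapply(1:20, function(i) {
    fit_spectral_slope(spectral_noise(16384, 300, slope = 1, seed = i), 300)
  }, numeric(1)))
  expect_lt(abs(sl1 + 1), 0.1)
})

test_that("band oscillations concentrate power at the configured frequency", {
  osc <- list(list(center = 10, bw = 2, amp = 4))
  x <- spectral_noise(8192, 300, slope = 1, oscillations = osc, seed = 9)
  psd <- welch_psd(x, 300, seg_sec = 4)
  in_band <- band_power(psd, 8, 12)
  out_band <- band_power(psd, 15, 19)
  expect_gt(in_band, 3 * out_band)
})

test_that("nonlinearity injection preserves the spectrum and is identity at zero", {
  x <- spectral_noise(4000, 300, slope = 1, seed = 13)
  expect_identical(inject_nonlinearity(x, 0), x)
  y <- inject_nonlinearity(x, 0.8)
  expect_length(y, length(x))
  expect_lt(max(abs(Mod(fft(y)) - Mod(fft(x)))) / max(Mod(fft(x))), 1e-10)
  expect_error(inject_nonlinearity(x, -1), ">= 0")
})

test_that("injected nonlinearity is what phase shuffling destroys", {
  gap <- vapply(1:20, function(i) {
    x <- spectral_noise(3000, 300, slope = 1, seed = 40 + i)
    y <- inject_nonlinearity(x, 1)
    d_out <- sample_entropy(phase_shuffle(y, seed = 70 + i)) - sample_entropy(y)
    d_in <- sample_entropy(phase_shuffle(x, seed = 90 + i)) - sample_entropy(x)
    d_out - d_in
  }, numeric(1))
  expect_gt(mean(gap), 0)
})

test_that("disc layout partitions channels into areas and binary regions", {
  lay <- disc_layout(64)
  expect_equal(nrow(lay), 64)
  expect_setequal(unique(lay$region), c("medial", "periphery"))
  expect_equal(sum(lay$region == "medial"), 24)
  expect_true(all(lay$area %in% c("frontal", "central", "parietal", "occipital",
                                  "left-temporal", "right-temporal")))
  expect_equal(anyDuplicated(lay$channel), 0)
  # every area non-empty at the default size
  expect_equal(dplyr::n_distinct(lay$area), 6)
})

test_that("cohort generation is deterministic with ground truth matching config", {
  cfg <- tiny_config(effect = list(slope = -0.3), seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$recordings, c2$recordings)
  expect_identical(c1$truth, c2$truth)
  expect_length(c1$recordings, 12)
  expect_equal(sort(unique(c1$truth$group)), c("control", "patient"))

  # effect applied only to patient medial channels
  med <- c1$truth$region == "medial"
  pat <- c1$truth$group == "patient"
  base_by_subj <- tapply(c1$truth$slope[!med], c1$truth$subject[!med], mean)
  med_by_subj <- tapply(c1$truth$slope[med], c1$truth$subject[med], mean)
  diff <- as.numeric(med_by_subj - base_by_subj[names(med_by_subj)])
  names(diff) <- names(med_by_subj)
  subj_grp <- c1$truth$group[match(names(diff), c1$truth$subject)]
  # baseline medial - periphery slope difference is 1.0 - 1.2 = -0.2;
  # patients add the configured -0.3 on medial channels
  expect_equal(unname(diff[subj_grp == "patient"]),
               rep(-0.3 - 0.2, sum(subj_grp == "patient")), tolerance = 1e-12)
  expect_equal(unname(diff[subj_grp == "control"]),
               rep(-0.2, sum(subj_grp == "control")), tolerance = 1e-12)
})

test_that("generated channels carry the configured spectral slope", {
  cfg <- tiny_config(n_per_group = 2L, duration = 30, subject_sd = 0,
                     effect = list(slope = 0), seed = 3,
                     oscillations = list())
  coh <- generate_cohort(cfg)
  sl <- unlist(lapply(coh$recordings, function(r) {
    apply(r$data, 1, fit_spectral_slope, fs = r$fs, fmin = 2, fmax = 60)
  }))
  truth_slopes <- coh$truth$slope
  expect_lt(abs(mean(sl) + mean(truth_slopes)), 0.15)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_per_group = 1), "at least 2")
  expect_error(cohort_config(fs = 0), "positive")
  expect_error(cohort_config(nonlinearity = c(medial = -1, periphery = 0)), ">= 0")
  expect_error(cohort_config(effect = list(slope = -0.2),
                             effect_region = character(0)), "effect_region")
  cfg <- tiny_config(effect_region = c("CH001", "NOPE"),
                     effect = list(slope = -0.1))
  expect_error(generate_cohort(cfg), "NOPE")
})
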