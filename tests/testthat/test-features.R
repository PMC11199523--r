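make_curve_tbl <- function(subjects, groups, channels, variants, grid,
                           value_fun) {
  tidyr::expand_grid(subject = subjects, channel = channels,
                     variant = variants, tau = grid) |>
    dplyr::mutate(group = groups[match(subject, subjects)],
                  sampen = value_fun(subject, channel, variant, tau))
}

test_that("per-channel feature vector has the 7 contracted entries", {
  grid <- c(4L, 8L, 12L, 16L, 19L, 22L, 28L, 32L, 36L, 48L, 59L, 70L, 80L)
  f <- channel_mse_features(grid, seq(2, 1, length.out = length(grid)))
  expect_length(f, 7)
  expect_named(f, c("kappa_full", "kappa_high", "kappa_mid", "kappa_low",
                    "kappa_vls", "peak", "peak_scale"))
  # strictly decreasing curve peaks at the smallest scale
  expect_equal(unname(f["peak_scale"]), 4)
  expect_equal(unname(f["peak"]), 2)
  # constant curve: all kappas equal the constant
  g <- channel_mse_features(grid, rep(1.3, length(grid)))
  expect_equal(unname(g[1:6]), rep(1.3, 6))
})

test_that("MSE feature table meets the 56/168 count contracts", {
  grid <- c(4L, 8L, 12L, 16L, 19L, 22L, 28L, 32L, 36L, 48L, 59L, 70L, 80L)
  layout <- disc_layout(16)
  subjects <- sprintf("s%02d", 1:6)
  groups <- rep(c("patient", "control"), each = 3)
  set.seed(41)
  one <- make_curve_tbl(subjects, groups, layout$channel, "org", grid,
                        function(s, c, v, t) runif(length(t), 1, 2))
  ft1 <- mse_feature_table(one, layout)
  expect_equal(ncol(ft1) - 2, 56)

  both <- make_curve_tbl(subjects, groups, layout$channel, c("org", "psf"),
                         grid, function(s, c, v, t) runif(length(t), 1, 2))
  ft3 <- mse_feature_table(both, layout)  # org + psf + derived nlc
  expect_equal(ncol(ft3) - 2, 168)
  expect_equal(nrow(ft3), 6)
  expect_true(all(c("subject", "group") %in% names(ft3)))
  # nlc columns are present and derived
  expect_true(any(grepl("^nlc_", names(ft3))))
})

test_that("degenerate curves give zero SD and collapsed region statistics", {
  grid <- c(4L, 8L, 12L, 16L, 19L, 22L, 28L, 32L, 36L, 48L, 59L, 70L, 80L)
  layout <- disc_layout(16)
  flat <- make_curve_tbl("s01", "patient", layout$channel, "org", grid,
                         function(s, c, v, t) rep(1.5, length(t)))
  ft <- mse_feature_table(flat, layout)
  sd_cols <- grep("_sd$", names(ft), value = TRUE)
  expect_true(all(ft[, sd_cols] == 0))
  expect_equal(unname(unlist(ft[1, "org_medial_kappa_full_mean"])), 1.5)
  expect_equal(unname(unlist(ft[1, "org_medial_kappa_full_max"])),
               unname(unlist(ft[1, "org_medial_kappa_full_min"])))
})

test_that("feature statistics are invariant to channel order", {
  grid <- c(4L, 8L, 16L, 32L)
  layout <- disc_layout(16)
  set.seed(43)
  tbl <- make_curve_tbl("s01", "patient", layout$channel, "org", grid,
                        function(s, c, v, t) runif(length(t), 1, 2))
  ft1 <- mse_feature_table(tbl, layout,
                           tibble::tibble(region = "full", x1 = 4L, x2 = 32L))
  shuffled <- tbl[sample(nrow(tbl)), ]
  ft2 <- mse_feature_table(shuffled, layout,
                           tibble::tibble(region = "full", x1 = 4L, x2 = 32L))
  expect_equal(ft1, ft2[, names(ft1)])
})

test_that("band definitions match the printed bounds including the beta gap", {
  b <- band_definitions()
  expect_equal(b$low[b$band == "delta"], 0.5)
  expect_equal(b$high[b$band == "alpha"], 12.5)
  expect_equal(b$low[b$band == "beta"], 15)
  expect_true(all(b$low < b$high))
})

test_that("PSD feature table meets the 45/180 count contracts", {
  layout <- disc_layout(16)
  set.seed(47)
  recs <- lapply(1:4, function(i) {
    mat <- matrix(rnorm(16 * 1500), nrow = 16,
                  dimnames = list(layout$channel, NULL))
    recording(sprintf("s%02d", i), ifelse(i <= 2, "patient", "control"),
              150, mat)
  })
  ft <- psd_band_features(recs, layout)
  expect_equal(ncol(ft) - 2, 180)
  base <- grep("_mean$", names(ft), value = TRUE)
  expect_length(base, 45)
  # normalized band powers over the printed bands sum to <= 1 (band gap)
  mean_cols <- grep("_all_mean$", names(ft), value = TRUE)
  expect_length(mean_cols, 5)
  sums <- rowSums(ft[, mean_cols])
  expect_true(all(sums <= 1 + 1e-8))
  expect_true(all(sums > 0))
})

test_that("a pure alpha tone concentrates normalized alpha power", {
  layout <- disc_layout(16)
  t <- seq(0, 20 - 1 / 150, by = 1 / 150)
  mat <- do.call(rbind, lapply(1:16, function(i) sin(2 * pi * 10 * t + i)))
  rownames(mat) <- layout$channel
  rec <- recording("s01", "patient", 150, mat)
  ft <- psd_band_features(list(rec), layout)
  alpha_cols <- grep("^psd_alpha_.*_mean$", names(ft), value = TRUE)
  expect_true(all(ft[, alpha_cols] > 0.95))
  expect_error(
    psd_band_features(list(recording("s", "g", 60,
                                     matrix(rnorm(300), 1,
                                            dimnames = list("A", NULL)))),
                      tibble::tibble(channel = "A", area = "frontal",
                                     region = "medial")),
    "band edge")
})
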