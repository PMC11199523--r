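test_that("kappa reduces to the mean for constant and linear curves", {
  tau <- 4:20
  expect_equal(kappa(tau, rep(1.7, length(tau)), 4, 20), 1.7)
  # linear a -> b: trapezoid gives (a + b) / 2
  lin <- seq(1, 3, length.out = length(tau))
  expect_equal(kappa(tau, lin, 4, 20), 2)
  expect_error(kappa(tau, lin, 20, 4), "x1 < x2")
})

test_that("kappa on a coarse grid agrees with a dense-grid integral", {
  f <- function(t) 1.5 + 0.4 * sin(t / 8) + 0.1 * log(t)
  coarse <- seq(4L, 80L, by = 8L)
  dense <- 4:80
  k_coarse <- kappa(coarse, f(coarse), 4, 80)
  k_dense <- kappa(dense, f(dense), 4, 80)
  expect_equal(k_coarse, k_dense, tolerance = 0.01)
})

test_that("kappa drops undefined points and renormalizes the span", {
  tau <- c(4, 8, 12, 16)
  s <- c(2, NA, NA, 2)
  expect_equal(kappa(tau, s, 4, 16), 2)
  expect_true(is.na(kappa(tau, c(2, NA, NA, NA), 4, 16)))
})

test_that("normalized group delta is antisymmetric and bounded", {
  expect_equal(delta_sampen(3, 1), 1)
  expect_equal(delta_sampen(5, 5), 0)
  expect_equal(delta_sampen(1, 3), -1)
  expect_true(is.na(delta_sampen(1, -1)))
  set.seed(19)
  a <- runif(100, 0.1, 5)
  b <- runif(100, 0.1, 5)
  expect_true(all(abs(delta_sampen(a, b)) < 2))
  expect_equal(delta_sampen(a, b), -delta_sampen(b, a))
})

test_that("channel-wise tests return t = 0, p = 1 for identical groups", {
  vals <- rnorm(6, mean = 2)
  kt <- tidyr::expand_grid(channel = c("c1", "c2"),
                           idx = 1:6) |>
    dplyr::mutate(kappa = rep(vals, 2))
  tbl <- dplyr::bind_rows(
    dplyr::mutate(kt, subject = paste0("p", idx), group = "patient"),
    dplyr::mutate(kt, subject = paste0("c", idx), group = "control")
  ) |>
    dplyr::mutate(variant = "org", region = "full")
  cmp <- channelwise_tests(tbl)
  expect_equal(cmp$t, c(0, 0))
  expect_equal(cmp$p, c(1, 1))
  expect_equal(cmp$delta_kappa, c(0, 0))
})

test_that("BH adjustment matches the reference step-up procedure", {
  set.seed(23)
  for (i in 1:20) {
    m <- sample(3:1000, 1)
    p <- runif(m)^sample(1:3, 1)
    # independent step-up implementation
    o <- order(p, decreasing = TRUE)
    q_ref <- numeric(m)
    prev <- 1
    for (k in seq_along(o)) {
      rank_i <- m - k + 1
      prev <- min(prev, p[o[k]] * m / rank_i)
      q_ref[o[k]] <- prev
    }
    expect_equal(p.adjust(p, "BH"), q_ref, tolerance = 1e-14)
  }
})

test_that("empirical power of the channel-wise test matches the analytic value", {
  set.seed(29)
  n <- 50
  shift <- 1
  nrep <- 400
  hits <- replicate(nrep, {
    t.test(rnorm(n, shift), rnorm(n))$p.value < 0.05
  })
  ncp <- shift / sqrt(2 / n)
  df <- 2 * n - 2
  tc <- qt(0.975, df)
  power_analytic <- 1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  expect_equal(mean(hits), power_analytic, tolerance = 0.05)
})

test_that("q-values never fall below p-values and counts are recorded", {
  set.seed(31)
  tbl <- tidyr::expand_grid(subject = sprintf("s%02d", 1:16),
                            channel = sprintf("ch%d", 1:12)) |>
    dplyr::mutate(group = ifelse(as.integer(substr(subject, 2, 3)) <= 8,
                                 "patient", "control"),
                  variant = "org", region = "full",
                  kappa = rnorm(dplyr::n(), 2, 0.3) +
                    ifelse(group == "patient" & channel %in% c("ch1", "ch2"), 1, 0))
  cmp <- channelwise_tests(tbl)
  ok <- !is.na(cmp$q)
  expect_true(all(cmp$q[ok] >= cmp$p[ok]))
  expect_type(attr(cmp, "n_sig_p"), "integer")
  expect_gte(attr(cmp, "n_sig_p"), attr(cmp, "n_sig_q"))
  expect_gt(attr(cmp, "n_sig_p"), 0)
})

test_that("area summaries aggregate by layout and produce valid CDFs", {
  set.seed(37)
  layout <- disc_layout(16)
  subs <- tidyr::expand_grid(subject = sprintf("s%02d", 1:12),
                             channel = layout$channel) |>
    dplyr::mutate(group = ifelse(as.integer(substr(subject, 2, 3)) <= 6,
                                 "patient", "control"),
                  variant = "org", region = "full",
                  kappa = rnorm(dplyr::n(), 2, 0.2))
  cmp <- channelwise_tests(subs)
  out <- area_summaries(cmp, subs, layout)
  expect_setequal(out$binary_region$region, c("medial", "periphery"))
  expect_equal(sum(out$area$n_channels), 16)
  cdf_ok <- out$cdf |>
    dplyr::group_by(area, group) |>
    dplyr::summarise(mono = !is.unsorted(frac),
                     top = max(frac), .groups = "drop")
  expect_true(all(cdf_ok$mono))
  expect_true(all(cdf_ok$top == 1))
})
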