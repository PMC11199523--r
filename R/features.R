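#' Canonical frequency bands
#'
#' The five conventional EEG/MEG bands as used by the band-power analysis.
#' Note the deliberate 12.5-15 Hz gap between alpha and beta.
#'
#' @return Tibble with columns `band`, `low`, `high` (Hz).
#' @export
band_definitions <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low = c(0.5, 4, 7.5, 15, 30),
    high = c(4, 7.5, 12.5, 30, 40)
  )
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the series is cut into Hann-windowed
#' segments with the given overlap, each segment's periodogram is computed,
#' and the results are averaged. One-sided output.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param seg_sec segment length in seconds (default 2).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return Tibble with columns `freq` (Hz) and `power` (density units).
#' @export
welch_psd <- function(x, fs, seg_sec = 2, overlap = 0.5) {
  nseg <- min(length(x), round(seg_sec * fs))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  u <- sum(win^2)
  nf <- nseg %/% 2 + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)]
    seg <- (seg - mean(seg)) * win
    P <- Mod(fft(seg))^2 / (fs * u)
    half <- P[seq_len(nf)]
    # fold negative frequencies into the one-sided estimate
    half[2:(nf - 1 + nseg %% 2)] <- 2 * half[2:(nf - 1 + nseg %% 2)]
    acc <- acc + half
  }
  tibble::tibble(freq = seq(0, nf - 1) * fs / nseg, power = acc / length(starts))
}

# trapezoidal band integral of a one-sided PSD
band_power <- function(psd, low, high) {
  keep <- psd$freq >= low & psd$freq <= high
  f <- psd$freq[keep]
  p <- psd$power[keep]
  if (length(f) < 2) return(0)
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Per-channel MSE features
#'
#' The seven features summarizing one channel's entropy-vs-scale curve:
#' kappa over the full, high, mid, low and very-low scale regions, the peak
#' entropy over the grid, and the scale at which the peak occurs (smallest
#' scale on ties).
#'
#' @param tau,sampen the channel's entropy curve.
#' @param regions scale-region table from [scale_regions()].
#' @return Named numeric vector of length 7 (`kappa_full`, ...,
#'   `kappa_vls`, `peak`, `peak_scale`); undefined values are `NA`.
#' @export
channel_mse_features <- function(tau, sampen, regions = scale_regions()) {
  ks <- vapply(seq_len(nrow(regions)), function(i) {
    kappa(tau, sampen, regions$x1[i], regions$x2[i])
  }, numeric(1))
  names(ks) <- paste0("kappa_", regions$region)
  if (all(is.na(sampen))) {
    peak <- NA_real_
    peak_scale <- NA_real_
  } else {
    peak <- max(sampen, na.rm = TRUE)
    peak_scale <- tau[!is.na(sampen) & sampen == peak][1]
  }
  c(ks, peak = peak, peak_scale = as.numeric(peak_scale))
}

#' MSE feature table for classification
#'
#' Builds, for every subject and every signal variant present in the curve
#' table, the 7 per-channel features and then 4 summary statistics (mean,
#' max, min, SD) of each feature across the channels of each binary sensor
#' region (medial / periphery): 7 x 2 x 4 = 56 features per variant, 168
#' with all three variants (org, psf, nlc). The nlc curves are formed as
#' psf minus org per scale when both are present.
#'
#' @param mse_tbl curve table from [cohort_mse()].
#' @param layout sensor layout (`channel`, `region`).
#' @param regions scale-region table.
#' @return Tibble: `subject`, `group`, then one column per feature, named
#'   `<variant>_<region>_<feature>_<stat>`.
#' @export
mse_feature_table <- function(mse_tbl, layout, regions = scale_regions()) {
  tbl <- mse_tbl
  if (all(c("org", "psf") %in% unique(tbl$variant))) {
    wide <- tidyr::pivot_wider(tbl, names_from = "variant", values_from = "sampen")
    nlc <- wide |>
      dplyr::mutate(variant = "nlc", sampen = .data$psf - .data$org) |>
      dplyr::select("subject", "group", "channel", "variant", "tau", "sampen")
    tbl <- dplyr::bind_rows(tbl, nlc)
  }
  per_ch <- tbl |>
    dplyr::group_by(.data$subject, .data$group, .data$channel, .data$variant) |>
    dplyr::group_modify(function(d, key) {
      f <- channel_mse_features(d$tau, d$sampen, regions)
      tibble::tibble(feature = names(f), value = unname(f))
    }) |>
    dplyr::ungroup() |>
    dplyr::inner_join(layout[, c("channel", "region")], by = "channel")

  stats_tbl <- per_ch |>
    dplyr::group_by(.data$subject, .data$group, .data$variant, .data$region,
                    .data$feature) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      max = max(.data$value, na.rm = TRUE),
      min = min(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("mean", "max", "min", "sd"),
                        names_to = "stat", values_to = "value") |>
    dplyr::mutate(name = paste(.data$variant, .data$region, .data$feature,
                               .data$stat, sep = "_"))

  tidyr::pivot_wider(stats_tbl[, c("subject", "group", "name", "value")],
                     names_from = "name", values_from = "value")
}

#' Band-power (PSD) feature table
#'
#' Welch spectrum per channel, normalized band power per canonical band
#' (band integral divided by the total 0.5-40 Hz integral), then 4 summary
#' statistics (mean, max, min, SD) across the channels of each of 9 sensor
#' ROIs: the 6 anatomical areas, the 2 binary regions and all sensors.
#' 5 bands x 9 ROIs = 45 base features; x 4 statistics = 180 values per
#' subject.
#'
#' @param recordings list of [recording()] objects.
#' @param layout sensor layout (`channel`, `area`, `region`).
#' @param bands band table from [band_definitions()].
#' @param seg_sec,overlap Welch parameters (see [welch_psd()]).
#' @param total_range frequency range for the normalization integral.
#' @return Tibble: `subject`, `group`, then `psd_<band>_<roi>_<stat>`
#'   columns.
#' @export
psd_band_features <- function(recordings, layout, bands = band_definitions(),
                              seg_sec = 2, overlap = 0.5,
                              total_range = c(0.5, 40)) {
  fs <- recordings[[1]]$fs
  if (fs <= 2 * max(bands$high)) {
    stop_invalid("fs (%g Hz) must exceed twice the highest band edge (%g Hz)",
                 fs, max(bands$high))
  }
  rows <- lapply(recordings, function(rec) {
    per_ch <- lapply(seq_len(nrow(rec$data)), function(c) {
      psd <- welch_psd(rec$data[c, ], rec$fs, seg_sec, overlap)
      tot <- band_power(psd, total_range[1], total_range[2])
      tibble::tibble(
        channel = rec$channels[c],
        band = bands$band,
        power = vapply(seq_len(nrow(bands)), function(i) {
          band_power(psd, bands$low[i], bands$high[i]) / tot
        }, numeric(1))
      )
    })
    out <- dplyr::bind_rows(per_ch)
    out$subject <- rec$subject
    out$group <- rec$group
    out
  })
  bp <- dplyr::bind_rows(rows)

  lay <- layout[, c("channel", "area", "region")]
  rois <- dplyr::bind_rows(
    dplyr::rename(lay[, c("channel", "area")], roi = "area"),
    dplyr::rename(lay[, c("channel", "region")], roi = "region"),
    tibble::tibble(channel = lay$channel, roi = "all")
  )
  stats_tbl <- dplyr::inner_join(bp, rois, by = "channel",
                                 relationship = "many-to-many") |>
    dplyr::group_by(.data$subject, .data$group, .data$band, .data$roi) |>
    dplyr::summarise(
      mean = mean(.data$power), max = max(.data$power),
      min = min(.data$power), sd = sd(.data$power),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("mean", "max", "min", "sd"),
                        names_to = "stat", values_to = "value") |>
    dplyr::mutate(name = paste("psd", .data$band, .data$roi, .data$stat, sep = "_"))

  tidyr::pivot_wider(stats_tbl[, c("subject", "group", "name", "value")],
                     names_from = "name", values_from = "value")
}
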