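#' Named scale-factor regions
#'
#' The five scale regions used throughout the analysis, in scale-factor
#' units: the full working range plus the three difference peaks and a
#' very-low-scale (high-frequency) band.
#'
#' @return Tibble with columns `region`, `x1`, `x2` (inclusive bounds).
#' @export
scale_regions <- function() {
  tibble::tibble(
    region = c("full", "high", "mid", "low", "vls"),
    x1 = c(4L, 48L, 28L, 16L, 4L),
    x2 = c(80L, 70L, 36L, 22L, 12L)
  )
}

#' Scale-region mean entropy (kappa)
#'
#' Mean of the entropy-vs-scale curve over a scale region, computed as the
#' trapezoidal integral over the grid points falling in `[x1, x2]` divided
#' by the span actually covered. Undefined (NA) grid points are dropped and
#' the span renormalized accordingly.
#'
#' @param tau integer scale factors (increasing).
#' @param sampen entropy values (NA where undefined).
#' @param x1,x2 inclusive region bounds in scale-factor units.
#' @return Kappa, or `NA_real_` with fewer than 2 defined points in the
#'   region.
#' @export
kappa <- function(tau, sampen, x1, x2) {
  if (x1 >= x2) stop_invalid("region bounds must satisfy x1 < x2")
  keep <- tau >= x1 & tau <= x2 & !is.na(sampen)
  t <- tau[keep]
  s <- sampen[keep]
  if (length(t) < 2) return(NA_real_)
  ord <- order(t)
  t <- t[ord]
  s <- s[ord]
  area <- sum(diff(t) * (s[-1] + s[-length(s)]) / 2)
  area / (t[length(t)] - t[1])
}

#' Normalized group difference
#'
#' Difference of two group means normalized by their average,
#' `2 (a - b) / (a + b)`. Serves both the per-scale entropy difference and
#' the region-level kappa difference; bounded by (-2, 2) whenever both
#' means are positive.
#'
#' @param a,b group means (vectorized).
#' @return Normalized difference (`NA` where `a + b == 0`).
#' @export
delta_sampen <- function(a, b) {
  denom <- a + b
  out <- 2 * (a - b) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Channel-wise group comparison of kappa
#'
#' Welch two-sample t-test per channel on the kappa values of one variant
#' and scale region, with Benjamini-Hochberg adjustment across channels.
#' The group difference is reported as the normalized delta of group means
#' ([delta_sampen()], first group minus second). Channels degenerate in
#' both groups (zero variance) are flagged and excluded from the FDR
#' family.
#'
#' @param kappa_tbl tibble with columns `subject`, `group`, `channel`,
#'   `variant`, `region`, `kappa`.
#' @param variant signal variant to test (`"org"`, `"psf"` or `"nlc"`).
#' @param region scale-region name (default `"full"`).
#' @param groups length-2 character: test computes group 1 minus group 2.
#'   Defaults to `c("patient", "control")` when present, else the sorted
#'   labels.
#' @param alpha significance threshold for the reported counts.
#' @return Tibble with per-channel `delta_kappa`, `t`, `p`, `q`,
#'   `excluded`; attributes `n_sig_p` and `n_sig_q` carry the significance
#'   counts at `alpha`.
#' @export
channelwise_tests <- function(kappa_tbl, variant = "org", region = "full",
                              groups = NULL, alpha = 0.05) {
  kt <- kappa_tbl[kappa_tbl$variant == variant & kappa_tbl$region == region, ]
  if (nrow(kt) == 0) stop_invalid("no rows for variant '%s', region '%s'", variant, region)
  labs <- unique(kt$group)
  if (is.null(groups)) {
    groups <- if (all(c("patient", "control") %in% labs)) {
      c("patient", "control")
    } else {
      sort(labs)
    }
  }
  if (!all(groups %in% labs)) stop_invalid("groups not found in kappa table")

  res <- lapply(split(kt, kt$channel), function(ch) {
    a <- ch$kappa[ch$group == groups[1]]
    b <- ch$kappa[ch$group == groups[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble::tibble(channel = ch$channel[1], delta_kappa = NA_real_,
                            t = NA_real_, p = NA_real_, excluded = TRUE))
    }
    dk <- delta_sampen(mean(a), mean(b))
    tt <- tryCatch(t.test(a, b), error = function(e) NULL)
    if (is.null(tt)) {
      tibble::tibble(channel = ch$channel[1], delta_kappa = dk,
                     t = NA_real_, p = NA_real_, excluded = TRUE)
    } else {
      tibble::tibble(channel = ch$channel[1], delta_kappa = dk,
                     t = unname(tt$statistic), p = tt$p.value, excluded = FALSE)
    }
  })
  out <- dplyr::bind_rows(res)
  out$q <- NA_real_
  ok <- !out$excluded
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  attr(out, "groups") <- groups
  attr(out, "n_sig_p") <- sum(out$p < alpha, na.rm = TRUE)
  attr(out, "n_sig_q") <- sum(out$q < alpha, na.rm = TRUE)
  out
}

#' Anatomical aggregation and kappa CDFs
#'
#' Aggregates a channel-wise comparison over the layout's anatomical areas
#' and the binary medial/periphery partition, and computes group-wise
#' empirical CDFs of per-subject area-averaged kappa.
#'
#' @param comparison output of [channelwise_tests()].
#' @param kappa_tbl the kappa table the comparison was computed from
#'   (same variant/region rows are selected by `variant`, `region`).
#' @param layout sensor layout tibble (`channel`, `area`, `region`).
#' @param variant,region variant and scale region for the CDF curves.
#' @param alpha significance threshold for the per-area counts.
#' @return List with tibbles `area` (per anatomical area), `binary_region`
#'   (medial vs periphery) and `cdf` (columns `area`, `group`, `kappa`,
#'   `frac`).
#' @export
area_summaries <- function(comparison, kappa_tbl, layout,
                           variant = "org", region = "full", alpha = 0.05) {
  missing_ch <- setdiff(comparison$channel, layout$channel)
  if (length(missing_ch) > 0) {
    stop_invalid("layout lacks channels: %s", paste(missing_ch, collapse = ", "))
  }
  cmp <- dplyr::inner_join(comparison,
                           layout[, c("channel", "area", "region")],
                           by = "channel")
  summarize_by <- function(tbl, key) {
    tbl |>
      dplyr::group_by(.data[[key]]) |>
      dplyr::summarise(
        n_channels = dplyr::n(),
        mean_delta_kappa = mean(.data$delta_kappa, na.rm = TRUE),
        n_sig_p = sum(.data$p < alpha, na.rm = TRUE),
        n_sig_q = sum(.data$q < alpha, na.rm = TRUE),
        .groups = "drop"
      )
  }
  area_tbl <- summarize_by(cmp, "area")
  region_tbl <- summarize_by(cmp, "region")

  kt <- kappa_tbl[kappa_tbl$variant == variant & kappa_tbl$region == region, ]
  kt <- dplyr::inner_join(kt, layout[, c("channel", "area")], by = "channel")
  per_subj <- kt |>
    dplyr::group_by(.data$area, .data$group, .data$subject) |>
    dplyr::summarise(kappa = mean(.data$kappa, na.rm = TRUE), .groups = "drop")
  cdf <- per_subj |>
    dplyr::group_by(.data$area, .data$group) |>
    dplyr::arrange(.data$kappa, .by_group = TRUE) |>
    dplyr::mutate(frac = seq_along(.data$kappa) / dplyr::n()) |>
    dplyr::ungroup()

  list(area = area_tbl, binary_region = region_tbl, cdf = cdf)
}
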