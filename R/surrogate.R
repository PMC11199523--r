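#' Phase-randomized surrogate of a time series
#'
#' Fourier transforms the series, replaces the phases of the positive
#' frequencies with iid uniform(0, 2*pi) draws (negative frequencies
#' conjugate-mirrored; DC and, for even length, the Nyquist bin kept real),
#' and inverts the transform. The surrogate has the original amplitude
#' spectrum bin-for-bin but no phase-dependent (nonlinear) structure.
#'
#' @param x finite numeric series.
#' @param seed integer seed for the phase draw.
#' @param n_realizations number of independent surrogates to return.
#' @return A numeric vector (one realization) or a list of numeric vectors.
#' @export
phase_shuffle <- function(x, seed = 1L, n_realizations = 1L) {
  if (!all(is.finite(x))) stop_invalid("input series must be finite")
  if (n_realizations < 1) stop_invalid("n_realizations must be >= 1")
  n <- length(x)
  X <- fft(x)
  half <- (n - 1) %/% 2              # strictly positive, non-Nyquist bins
  out <- with_seed(seed, lapply(seq_len(n_realizations), function(k) {
    phases <- runif(half, 0, 2 * pi)
    Y <- X
    if (half > 0) {
      idx <- 2:(half + 1)
      Y[idx] <- Mod(X[idx]) * exp(1i * phases)
      Y[n + 2 - idx] <- Conj(Y[idx])
    }
    # DC untouched; even n leaves the Nyquist bin (n/2 + 1) real as-is
    Re(fft(Y, inverse = TRUE)) / n
  }))
  if (n_realizations == 1L) out[[1]] else out
}

#' Entropy attributable to phase structure
#'
#' The nonlinear component of the scale-region entropy: the surrogate's
#' kappa minus the original's. Positive values mean phase randomization
#' raised the entropy, i.e. the original carried phase-dependent order.
#'
#' @param kappa_psf kappa of the phase-shuffled series.
#' @param kappa_org kappa of the original series.
#' @return `kappa_psf - kappa_org` (`NA` propagates).
#' @export
kappa_nlc <- function(kappa_psf, kappa_org) {
  kappa_psf - kappa_org
}

#' Group difference of the nonlinear component
#'
#' Unnormalized difference of group-mean residues and the same difference
#' normalized by the mean of the two residues.
#'
#' @param nlc_a,nlc_b per-subject kappa_nlc values for the two groups
#'   (group A minus group B).
#' @return List with `delta` and `delta_norm` (the latter `NA` when the
#'   residue sum is zero).
#' @export
delta_kappa_nlc <- function(nlc_a, nlc_b) {
  if (length(nlc_a) == 0 || length(nlc_b) == 0) stop_invalid("both groups must be non-empty")
  ma <- mean(nlc_a, na.rm = TRUE)
  mb <- mean(nlc_b, na.rm = TRUE)
  delta <- ma - mb
  denom <- ma + mb
  list(delta = delta,
       delta_norm = if (isTRUE(all.equal(denom, 0))) NA_real_ else 2 * delta / denom)
}

#' Amplitude-vs-phase balance of two sensor areas
#'
#' For each participant and each of two areas, averages the normalized
#' kappa difference (relative to the other group's channel means) across
#' the area's sensors for the surrogate (PSF) and nonlinear (NLC)
#' components, forms `R = K_psf / (K_psf + K_nlc)`, and compares the areas
#' via the ratio `R' = R1 / R2` and the difference `dR = R1 - R2`. Groups
#' are then compared on `R'` and `dR` with Welch t-tests.
#'
#' @param kappa_tbl kappa table with columns `subject`, `group`, `channel`,
#'   `variant` (must contain `"psf"` and `"nlc"`), `kappa`.
#' @param layout sensor layout with columns `channel`, `area`.
#' @param area1,area2 names of the two areas to contrast.
#' @param scale_region scale-region name the kappa values are taken from
#'   (default `"full"`).
#' @param per_participant if `FALSE`, `K` is computed from group-level mean
#'   kappa differences instead of per-participant ones.
#' @return List with per-participant tibble `ratios` (columns `subject`,
#'   `group`, `R1`, `R2`, `R_ratio`, `R_diff`) and Welch test results
#'   `test_ratio`, `test_diff` (absent when `per_participant = FALSE`;
#'   then `ratios` has one row per group).
#' @export
region_ratio <- function(kappa_tbl, layout, area1, area2,
                         scale_region = "full", per_participant = TRUE) {
  for (a in c(area1, area2)) {
    if (!a %in% layout$area) stop_invalid("area '%s' not present in layout", a)
  }
  kt <- dplyr::filter(kappa_tbl, .data$variant %in% c("psf", "nlc"),
                      .data$region == scale_region)
  kt <- dplyr::inner_join(kt, layout[, c("channel", "area")], by = "channel")
  kt <- dplyr::filter(kt, .data$area %in% c(area1, area2))
  groups <- sort(unique(kt$group))
  if (length(groups) != 2) stop_invalid("kappa table must contain exactly two groups")

  # per-channel mean kappa of the *other* group, the reference for the
  # normalized per-participant difference
  other_mean <- kt |>
    dplyr::group_by(.data$group, .data$channel, .data$variant, .data$area) |>
    dplyr::summarise(ref = mean(.data$kappa, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(group = ifelse(.data$group == groups[1], groups[2], groups[1]))

  dk <- dplyr::inner_join(kt, other_mean,
                          by = c("group", "channel", "variant", "area")) |>
    dplyr::mutate(dkappa = 2 * (.data$kappa - .data$ref) / (.data$kappa + .data$ref))

  if (per_participant) {
    K <- dk |>
      dplyr::group_by(.data$subject, .data$group, .data$area, .data$variant) |>
      dplyr::summarise(K = mean(.data$dkappa, na.rm = TRUE), .groups = "drop")
    keys <- c("subject", "group")
  } else {
    K <- dk |>
      dplyr::group_by(.data$group, .data$area, .data$variant) |>
      dplyr::summarise(K = mean(.data$dkappa, na.rm = TRUE), .groups = "drop")
    keys <- "group"
  }

  wide <- tidyr::pivot_wider(K, names_from = "variant", values_from = "K")
  wide$R <- ifelse(wide$psf + wide$nlc == 0, NA_real_,
                   wide$psf / (wide$psf + wide$nlc))
  r1 <- wide[wide$area == area1, c(keys, "R")]
  r2 <- wide[wide$area == area2, c(keys, "R")]
  names(r1)[names(r1) == "R"] <- "R1"
  names(r2)[names(r2) == "R"] <- "R2"
  ratios <- dplyr::inner_join(r1, r2, by = keys) |>
    dplyr::mutate(R_ratio = .data$R1 / .data$R2, R_diff = .data$R1 - .data$R2)

  out <- list(ratios = ratios)
  if (per_participant) {
    g1 <- ratios$group == groups[1]
    out$test_ratio <- t.test(ratios$R_ratio[g1], ratios$R_ratio[!g1])
    out$test_diff <- t.test(ratios$R_diff[g1], ratios$R_diff[!g1])
  }
  out
}
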