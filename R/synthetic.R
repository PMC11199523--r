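#' Colored noise with band oscillations
#'
#' Draws white Gaussian noise and shapes its spectrum in the frequency
#' domain: the amplitude at frequency f is multiplied by `f^(-slope/2)`
#' (so the power spectrum follows `f^-slope`) plus Gaussian band bumps.
#' The result is standardized to zero mean and unit variance.
#'
#' @param n number of samples (>= 16).
#' @param fs sampling rate in Hz.
#' @param slope spectral exponent beta of the `1/f^beta` power law (0 =
#'   white noise).
#' @param oscillations list of band specs, each a list/vector with elements
#'   `center` (Hz), `bw` (full width, Hz) and `amp` (amplitude relative to
#'   the 1/f envelope at the band center).
#' @param seed integer seed; identical arguments give identical output.
#' @return Numeric series of length `n`.
#' @export
spectral_noise <- function(n, fs, slope = 1, oscillations = list(), seed = 1L) {
  if (n < 16) stop_invalid("n must be >= 16")
  if (fs <= 0) stop_invalid("fs must be positive")
  w <- with_seed(seed, rnorm(n))
  W <- fft(w)
  f <- seq(0, n - 1) * fs / n
  half <- (n - 1) %/% 2
  fpos <- f[2:(half + 1)]
  mask <- rep(0, n)
  base <- fpos^(-slope / 2)
  bump <- rep(0, length(fpos))
  for (osc in oscillations) {
    osc <- as.list(osc)
    s <- osc$bw / 2
    bump <- bump + osc$amp * osc$center^(-slope / 2) *
      exp(-(fpos - osc$center)^2 / (2 * s^2))
  }
  mask[2:(half + 1)] <- base + bump
  mask[n + 2 - (2:(half + 1))] <- mask[2:(half + 1)]
  if (n %% 2 == 0) {
    fn <- fs / 2
    mask[n / 2 + 1] <- fn^(-slope / 2)
  }
  x <- Re(fft(W * mask, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Inject phase-coupled (nonlinear) structure
#'
#' Adds a lag-smoothed quadratic self-coupling term to the series and then
#' re-imposes the original amplitude spectrum, so the output has exactly
#' the input's power spectrum but phase-dependent structure that phase
#' randomization destroys. With `strength = 0` the input is returned
#' unchanged. The operation is deterministic; `seed` is accepted for
#' interface stability only.
#'
#' @param x numeric series.
#' @param strength dimensionless coupling weight (>= 0).
#' @param lag delay (samples) of the quadratic term.
#' @param width moving-average width (samples) smoothing the quadratic term.
#' @param seed unused; the operation is deterministic.
#' @return Numeric series, same length and amplitude spectrum as `x`.
#' @export
inject_nonlinearity <- function(x, strength, lag = 3L, width = 5L, seed = NULL) {
  if (strength < 0) stop_invalid("strength must be >= 0")
  if (strength == 0) return(x)
  n <- length(x)
  q <- stats::filter(x^2, rep(1 / width, width), sides = 2, circular = TRUE)
  q <- as.numeric(q)
  q <- c(q[(n - lag + 1):n], q[1:(n - lag)])  # circular delay
  q <- (q - mean(q)) / sd(q)
  y <- x + strength * q
  # restore the exact amplitude spectrum of x, keeping y's phases
  X <- fft(x)
  Y <- fft(y)
  phase <- Y / ifelse(Mod(Y) == 0, 1, Mod(Y))
  Re(fft(Mod(X) * phase, inverse = TRUE)) / n
}

#' Synthetic disc sensor layout
#'
#' Places channels on a unit disc by a sunflower (golden-angle) pattern,
#' labels the innermost fraction as the medial parieto-occipital region and
#' the rest as periphery, and assigns each channel one of six anatomical
#' areas (frontal, central, parietal, occipital, left/right temporal) from
#' its position (+y is anterior).
#'
#' @param n_channels number of sensors (>= 16).
#' @param n_medial number of sensors in the medial region (default 3/8 of
#'   the channels, i.e. 24 of 64).
#' @return Tibble with columns `channel`, `x`, `y`, `area`, `region`.
#' @export
disc_layout <- function(n_channels = 64L, n_medial = round(0.375 * n_channels)) {
  if (n_channels < 16) stop_invalid("need at least 16 channels")
  i <- seq_len(n_channels)
  r <- sqrt((i - 0.5) / n_channels)
  th <- i * pi * (3 - sqrt(5))
  x <- r * cos(th)
  y <- r * sin(th)
  ord <- order(r)
  region <- character(n_channels)
  region[ord[seq_len(n_medial)]] <- "medial"
  region[ord[-seq_len(n_medial)]] <- "periphery"
  # anterior angle: 0 = straight ahead (+y), positive clockwise (to +x)
  phi <- atan2(x, y)
  area <- ifelse(region == "medial",
                 ifelse(y >= 0, "central", "parietal"),
                 ifelse(abs(phi) <= pi / 3, "frontal",
                        ifelse(abs(phi) >= 2 * pi / 3, "occipital",
                               ifelse(phi > 0, "right-temporal", "left-temporal"))))
  tibble::tibble(
    channel = sprintf("CH%03d", i),
    x = x, y = y, area = area, region = region
  )
}

#' Configuration for a synthetic two-group cohort
#'
#' Defines the recording geometry and the generative parameters of both
#' groups. Controls receive the baseline `slope` and `nonlinearity` (per
#' binary region); patients additionally receive `effect` offsets on the
#' channels of `effect_region`.
#'
#' Direction of the slope effect: over the analyzed scale range (after
#' coarse-graining, with the tolerance fixed at scale 1), a steeper
#' `1/f` background keeps more of its variance and therefore yields
#' *higher* sample entropy and kappa. A positive slope offset is thus the
#' entropy-raising direction at those scales, and the lower baseline slope
#' of the medial region gives it the lower kappa observed medially.
#'
#' @param n_per_group subjects per group; a scalar or a length-2 vector
#'   `c(patients, controls)`. Defaults to the 49 / 98 split of the study
#'   cohort.
#' @param n_channels,fs,duration recording geometry (default 64 channels,
#'   600 Hz, 240 s).
#' @param slope baseline spectral exponent per region,
#'   `c(medial = ..., periphery = ...)`.
#' @param oscillations shared list of band specs (see [spectral_noise()]).
#' @param nonlinearity baseline phase-coupling strength per region.
#' @param effect list of patient-group offsets `slope` and `nonlinearity`
#'   applied inside `effect_region`.
#' @param effect_region `"medial"`, `"periphery"`, or explicit channel names.
#' @param subject_sd between-subject standard deviation of the spectral
#'   exponent (one offset per subject, shared across that subject's
#'   channels); models inter-individual variability of the 1/f background.
#' @param seed integer master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(49L, 98L),
                          n_channels = 64L,
                          fs = 600,
                          duration = 240,
                          slope = c(medial = 1.0, periphery = 1.2),
                          oscillations = list(
                            list(center = 10, bw = 2, amp = 1.0),
                            list(center = 20, bw = 5, amp = 0.3)
                          ),
                          nonlinearity = c(medial = 0.4, periphery = 0.4),
                          effect = list(slope = 0.2, nonlinearity = 0),
                          effect_region = "medial",
                          subject_sd = 0.05,
                          seed = 1L) {
  if (fs <= 0) stop_invalid("fs must be positive")
  if (duration <= 0) stop_invalid("duration must be positive")
  if (any(n_per_group < 2)) stop_invalid("need at least 2 subjects per group")
  if (any(nonlinearity < 0)) stop_invalid("nonlinearity strength must be >= 0")
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  effect <- modifyList(list(slope = 0, nonlinearity = 0), as.list(effect))
  has_effect <- effect$slope != 0 || effect$nonlinearity != 0
  if (has_effect && length(effect_region) == 0) {
    stop_invalid("non-zero configured effect requires a non-empty effect_region")
  }
  structure(list(
    n_per_group = as.integer(n_per_group), n_channels = as.integer(n_channels),
    fs = fs, duration = duration, slope = slope, oscillations = oscillations,
    nonlinearity = nonlinearity, effect = effect,
    effect_region = effect_region, subject_sd = subject_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a synthetic two-group cohort
#'
#' Simulates one multichannel recording per subject under the group and
#' region parameters of the configuration, together with the sensor layout
#' and a ground-truth table recording every generating parameter.
#'
#' @param config a [cohort_config()].
#' @return List with elements `recordings` (list of [recording()]),
#'   `layout` (tibble) and `truth` (tibble: subject, group, channel,
#'   region, area, slope, nonlinearity).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  layout <- disc_layout(config$n_channels)
  eff_ch <- if (identical(config$effect_region, "medial") ||
                identical(config$effect_region, "periphery")) {
    layout$channel[layout$region == config$effect_region]
  } else {
    unknown <- setdiff(config$effect_region, layout$channel)
    if (length(unknown) > 0) {
      stop_invalid("effect_region channels not in layout: %s",
                   paste(unknown, collapse = ", "))
    }
    config$effect_region
  }
  n <- round(config$fs * config$duration)
  groups <- rep(c("patient", "control"), config$n_per_group)
  subjects <- sprintf("sub%03d", seq_along(groups))

  truth <- vector("list", length(subjects))
  recordings <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    mat <- matrix(0, nrow = config$n_channels, ncol = n,
                  dimnames = list(layout$channel, NULL))
    subj_offset <- with_seed(derive_seed(config$seed, "subj", s),
                             rnorm(1, 0, config$subject_sd))
    slope_ch <- config$slope[layout$region] + subj_offset
    nlc_ch <- config$nonlinearity[layout$region]
    if (groups[s] == "patient") {
      in_eff <- layout$channel %in% eff_ch
      slope_ch[in_eff] <- slope_ch[in_eff] + config$effect$slope
      nlc_ch[in_eff] <- pmax(0, nlc_ch[in_eff] + config$effect$nonlinearity)
    }
    for (c in seq_len(config$n_channels)) {
      sd_seed <- derive_seed(config$seed, s, c)
      x <- spectral_noise(n, config$fs, slope_ch[c], config$oscillations,
                          seed = sd_seed)
      mat[c, ] <- inject_nonlinearity(x, nlc_ch[c])
    }
    recordings[[s]] <- recording(subjects[s], groups[s], config$fs, mat)
    truth[[s]] <- tibble::tibble(
      subject = subjects[s], group = groups[s], channel = layout$channel,
      region = layout$region, area = layout$area,
      slope = unname(slope_ch), nonlinearity = unname(nlc_ch)
    )
  }
  list(recordings = recordings, layout = layout,
       truth = dplyr::bind_rows(truth))
}
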