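#' Sample entropy parameters
#'
#' @param m template length in points (default 2).
#' @param r tolerance as a fraction of the reference series' standard
#'   deviation (default 0.2).
#' @param strict if `TRUE`, points match when their absolute difference is
#'   strictly below the tolerance; the default (`FALSE`) uses the
#'   Richman-Moorman convention `<= r`.
#' @return A list of class `sampen_params`.
#' @export
sampen_params <- function(m = 2L, r = 0.2, strict = FALSE) {
  if (m < 1) stop_invalid("m must be >= 1")
  if (r <= 0) stop_invalid("r must be positive")
  structure(list(m = as.integer(m), r = r, strict = isTRUE(strict)),
            class = "sampen_params")
}

#' Coarse-grain a time series
#'
#' Averages the series over consecutive non-overlapping windows of `tau`
#' samples; the j-th coarse sample is the mean of original samples
#' `(j-1)*tau + 1` through `j*tau` (1-based). A trailing remainder shorter
#' than `tau` is discarded, so the output has `floor(N / tau)` samples.
#'
#' @param x numeric series.
#' @param tau integer scale factor (>= 1).
#' @return Numeric vector of length `floor(length(x) / tau)`.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (tau < 1) stop_invalid("scale factor tau must be >= 1")
  n <- length(x)
  if (tau > n) stop_invalid("tau (%d) exceeds series length (%d)", tau, n)
  if (tau == 1L) return(as.numeric(x))
  nw <- n %/% tau
  colMeans(matrix(x[seq_len(nw * tau)], nrow = tau))
}

#' Sample entropy of a series
#'
#' Negative natural logarithm of the conditional probability that template
#' sequences matching for `m` consecutive points (Chebyshev distance within
#' the tolerance, self-matches excluded) remain matched at point `m + 1`.
#'
#' The tolerance is `params$r` times the standard deviation of `ref` (by
#' default the series itself). Passing the original-scale series as `ref`
#' implements the multiscale convention of fixing the tolerance once at
#' scale 1 and reusing it for every coarse-grained scale.
#'
#' @param x numeric series.
#' @param params a [sampen_params()] object.
#' @param ref reference series used to resolve the relative tolerance
#'   (defaults to `x`).
#' @param r_abs absolute tolerance; overrides `params$r` and `ref` if given.
#' @return Sample entropy (>= 0), or `NA_real_` when undefined (zero
#'   variance, or no template matches at length m or m + 1).
#' @export
sample_entropy <- function(x, params = sampen_params(), ref = x, r_abs = NULL) {
  m <- params$m
  n <- length(x)
  if (n <= m + 1) stop_invalid("series length (%d) must exceed m + 1", n)
  if (is.null(r_abs)) {
    s <- sd(ref)
    if (!is.finite(s) || s == 0) return(NA_real_)
    r_abs <- params$r * s
  }
  counts <- sampen_counts(as.numeric(x), m, r_abs, params$strict)
  if (counts[1] == 0 || counts[2] == 0) return(NA_real_)
  -log(counts[2] / counts[1])
}

#' Default multiscale grid
#'
#' Approximately log-spaced unique integer scale factors. With the defaults
#' this yields 38 scales from 4 to 120, matching the analysis' working range
#' (1200 coarse samples remain at the largest scale for a 4-minute record at
#' 600 Hz).
#'
#' @param n_scales number of scales.
#' @param from,to first and last scale factor.
#' @return Strictly increasing integer vector of length `n_scales`.
#' @export
scale_grid <- function(n_scales = 38L, from = 4L, to = 120L) {
  if (from < 1 || to <= from) stop_invalid("need 1 <= from < to")
  if (n_scales > to - from + 1) {
    stop_invalid("cannot place %d unique integers in [%d, %d]", n_scales, from, to)
  }
  len <- n_scales
  repeat {
    g <- unique(round(exp(seq(log(from), log(to), length.out = len))))
    if (length(g) >= n_scales) break
    len <- len + 1L
  }
  # thin evenly if over-generated
  as.integer(sort(g[round(seq(1, length(g), length.out = n_scales))]))
}

#' Multiscale entropy curve
#'
#' Sample entropy of progressively coarse-grained versions of the series,
#' one value per scale factor. The tolerance is resolved once from the
#' standard deviation of the scale-1 series and reused at every scale, so
#' the variance lost to coarse-graining is reflected in the curve.
#'
#' @param x numeric series.
#' @param grid integer scale factors (strictly increasing).
#' @param params a [sampen_params()] object.
#' @return A tibble with columns `tau`, `sampen` (`NA` where undefined).
#' @export
mse_curve <- function(x, grid = scale_grid(), params = sampen_params()) {
  grid <- as.integer(grid)
  if (is.unsorted(grid, strictly = TRUE)) stop_invalid("scale grid must be strictly increasing")
  if (grid[1] < 1) stop_invalid("scale factors must be >= 1")
  n <- length(x)
  if (n %/% max(grid) <= params$m + 1) {
    stop_invalid("series too short (N = %d) for largest scale %d with m = %d",
                 n, max(grid), params$m)
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    return(tibble::tibble(tau = grid, sampen = NA_real_))
  }
  r_abs <- params$r * s
  ent <- vapply(grid, function(tau) {
    sample_entropy(coarse_grain(x, tau), params, r_abs = r_abs)
  }, numeric(1))
  if (all(is.na(ent))) warning("all scales undefined (no template matches)")
  tibble::tibble(tau = grid, sampen = ent)
}

#' Equivalent sampling rate of a coarse-grained series
#'
#' Averaging over windows of `tau` samples downsamples the record; the
#' resulting effective rate is `fs / tau` (e.g. 600 Hz at scale 4 becomes
#' 150 Hz).
#'
#' @param fs sampling rate in Hz.
#' @param tau integer scale factor (>= 1).
#' @return Rate in Hz.
#' @export
esr <- function(fs, tau) {
  if (any(tau < 1)) stop_invalid("tau must be >= 1")
  if (fs <= 0) stop_invalid("fs must be positive")
  fs / tau
}

#' Maximum detectable frequency at a scale
#'
#' Half the equivalent sampling rate (Nyquist): `fs / (2 * tau)`.
#'
#' @inheritParams esr
#' @return Frequency in Hz.
#' @export
max_detectable_freq <- function(fs, tau) {
  esr(fs, tau) / 2
}
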