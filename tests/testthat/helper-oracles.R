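# Independent brute-force oracles and small fixtures used across tests.

# O(N^2) double-loop sample entropy, written against the definition only:
# counts matching template pairs (Chebyshev distance, self-matches excluded)
# at lengths m and m+1 over the first N - m templates.
sampen_bruteforce <- function(x, m, r_abs, strict = FALSE) {
  N <- length(x)
  nt <- N - m
  B <- 0
  A <- 0
  cmp <- if (strict) function(d) d < r_abs else function(d) d <= r_abs
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      ok <- TRUE
      for (k in 0:(m - 1)) {
        if (!cmp(abs(x[i + k] - x[j + k]))) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        B <- B + 1
        if (cmp(abs(x[i + m] - x[j + m]))) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# least-squares log-log spectral slope of a series (periodogram based)
fit_spectral_slope <- function(x, fs, fmin = 1, fmax = fs / 2 * 0.8) {
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  f <- seq(0, n - 1) * fs / n
  keep <- f >= fmin & f <= fmax
  unname(coef(lm(log(P[keep]) ~ log(f[keep])))[2])
}

# small cohort configuration used by several pipeline-level tests
tiny_config <- function(...) {
  args <- modifyList(list(
    n_per_group = 6L, n_channels = 16L, fs = 150, duration = 8,
    oscillations = list(list(center = 10, bw = 2, amp = 1)),
    nonlinearity = c(medial = 0, periphery = 0),
    subject_sd = 0.05
  ), list(...))
  do.call(cohort_config, args)
}

tiny_grid <- c(2L, 4L, 6L, 8L)
tiny_regions <- tibble::tibble(region = c("full", "low"),
                               x1 = c(2L, 2L), x2 = c(8L, 4L))

# The desk-scale recovery study is shared by several acceptance checks;
# computed once per test run and cached.
.recovery_cache <- new.env(parent = emptyenv())
get_recovery_result <- function() {
  if (!exists("res", envir = .recovery_cache)) {
    st <- recovery_study(seed = 101L)
    res <- run_pipeline(st$config, out_dir = NULL, grid = st$grid,
                        fspec = st$fspec, clf_config = st$clf_config)
    assign("res", res, envir = .recovery_cache)
  }
  get("res", envir = .recovery_cache)
}
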