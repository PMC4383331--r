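# Discrete Stockwell (S-) transform.
#
# Conventions (documented once, tested everywhere):
#  * The transform is computed on the periodic extension (circular
#    convolution) — the standard FFT S-transform algorithm.
#  * Real input is first replaced by its analytic extension (negative
#    frequency half of the spectrum zeroed, positive half doubled).
#    For a real signal the negative-frequency image otherwise
#    interferes with voices above ~N/4 and breaks the localization of
#    a pure tone near the Nyquist voice; with the analytic extension a
#    unit tone at voice k has constant magnitude W(|k - k'|) across
#    voices k', exactly maximal at k' = k.
#  * For voice k (frequency f = k/N cycles/sample) the analysis window
#    is a sampled Gaussian normalized to unit sum, so the
#    voice-summation identity sum_t S[t, k] == Z[k] (the DFT of the
#    analytic signal) holds exactly.
#  * Two kernel variants are kept:
#      "paper"   w(t) prop. exp(-pi t^2 f^2)   (narrower window)
#      "classic" w(t) prop. exp(-t^2 f^2 / 2)  (sigma = 1/f)
#  * The zero voice is set to the signal mean (the kernel is
#    degenerate at f = 0).

.st_cache <- new.env(parent = emptyenv())

st_gauss <- function(d, f, kernel) {
  switch(kernel,
         paper = exp(-pi * d^2 * f^2),
         classic = exp(-d^2 * f^2 / 2),
         stop_config("stockwell: unknown kernel '%s'", kernel))
}

st_window_spectrum <- function(n, k, kernel) {
  d <- ((0:(n - 1) + floor(n / 2)) %% n) - floor(n / 2)  # wrapped lag
  w <- st_gauss(d, k / n, kernel)
  w <- w / sum(w)
  Re(stats::fft(w))  # even window: real spectrum
}

# Spectrum multiplier of the analytic extension (even/odd n).
analytic_multiplier <- function(n) {
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

#' Discrete Stockwell transform
#'
#' Computes the S-transform of a real signal for all voices
#' `0..floor(N/2)` via the FFT algorithm: for voice k, the inverse FFT
#' of the frequency-shifted analytic spectrum `Z[m + k]` multiplied by
#' the (unit-sum) Gaussian window spectrum.  Returns the magnitude map
#' (time x voice) with the complex coefficients retained.
#'
#' @param x real numeric vector, length >= 8, finite.
#' @param fs sampling rate, Hz.
#' @param t0_ms time of the first sample relative to the stimulus, ms
#'   (e.g. `-200` for a standard epoch).
#' @param kernel `"paper"` (default) or `"classic"` Gaussian width; see
#'   the package vignette.
#' @param f_max optional frequency ceiling, Hz: voices above it are not
#'   computed (an efficiency cap used by the grid search; the default
#'   `NULL` computes every voice up to Nyquist).
#' @return an object of class `"st_map"` with fields `magnitudes`
#'   (time bins x frequency voices, non-negative), `coefficients`
#'   (complex), `time_axis` (ms), `freq_axis` (Hz, spacing `fs/N`),
#'   `fs`, `kernel`.
#' @export
stockwell <- function(x, fs, t0_ms = 0, kernel = c("paper", "classic"),
                      f_max = NULL) {
  kernel <- match.arg(kernel)
  if (length(x) < 8)
    stop_config("stockwell: signal length must be >= 8 (got %d)", length(x))
  if (any(!is.finite(x)))
    stop_config("stockwell: signal contains non-finite values")
  n <- length(x)
  Z <- stats::fft(x) * analytic_multiplier(n)
  n_voice <- floor(n / 2) + 1L
  if (!is.null(f_max))
    n_voice <- min(n_voice, floor(f_max * n / fs) + 1L)
  ks <- seq_len(n_voice - 1L)
  # all voices at once: unit-sum window spectra and shifted spectra as
  # columns, one matrix FFT each; window spectra are cached per
  # (n, kernel, n_voice) since every epoch shares them
  key <- sprintf("%d|%s|%d", n, kernel, n_voice)
  cached <- get0(key, envir = .st_cache)
  if (is.null(cached)) {
    d <- ((0:(n - 1) + floor(n / 2)) %% n) - floor(n / 2)    # wrapped lag
    W <- st_gauss(outer(d, ks / n), 1, kernel)
    W <- Re(stats::mvfft(sweep(W, 2, colSums(W), `/`)))
    cached <- list(W = W,
                   shift_idx = outer(seq_len(n) - 1L, ks, `+`) %% n + 1L)
    assign(key, cached, envir = .st_cache)
  }
  S <- cbind(mean(x) + 0i,
             stats::mvfft(matrix(Z[cached$shift_idx], n) * cached$W,
                          inverse = TRUE) / n)
  structure(
    list(magnitudes = Mod(S), coefficients = S,
         time_axis = t0_ms + (seq_len(n) - 1) / fs * 1000,
         freq_axis = (0:(n_voice - 1L)) * fs / n,
         fs = fs, kernel = kernel),
    class = "st_map")
}

#' Brute-force reference S-transform
#'
#' Direct summation of the discretized defining integral, voice by
#' voice and time bin by time bin (O(N^2) per voice), under the same
#' conventions as [stockwell()] (periodic extension, analytic signal,
#' unit-sum window).  Everything — including the analytic extension —
#' is computed by naive O(N^2) summation, so this oracle shares no
#' FFT code path with the implementation it checks.
#'
#' @inheritParams stockwell
#' @return an `"st_map"`.
#' @export
stockwell_reference <- function(x, fs, t0_ms = 0,
                                kernel = c("paper", "classic")) {
  kernel <- match.arg(kernel)
  n <- length(x)
  tau <- 0:(n - 1)
  # analytic signal by naive DFT / inverse DFT
  Z <- vapply(0:(n - 1), function(m)
    sum(x * exp(-2i * pi * m * tau / n)), 0i) * analytic_multiplier(n)
  z <- vapply(tau, function(t)
    sum(Z * exp(2i * pi * (0:(n - 1)) * t / n)), 0i) / n
  n_voice <- floor(n / 2) + 1L
  S <- matrix(0 + 0i, n, n_voice)
  S[, 1] <- sum(x) / n
  for (k in seq_len(n_voice - 1L)) {
    f <- k / n
    lag_w <- function(d) {
      d <- ((d + floor(n / 2)) %% n) - floor(n / 2)  # wrap to [-n/2, n/2)
      st_gauss(d, f, kernel)
    }
    norm <- sum(lag_w(tau))
    phase <- exp(-2i * pi * f * tau)
    for (j in seq_len(n)) {
      S[j, k + 1L] <- sum(z * lag_w((j - 1) - tau) * phase) / norm
    }
  }
  structure(
    list(magnitudes = Mod(S), coefficients = S,
         time_axis = t0_ms + (seq_len(n) - 1) / fs * 1000,
         freq_axis = (0:(n_voice - 1L)) * fs / n,
         fs = fs, kernel = kernel),
    class = "st_map")
}

#' @export
print.st_map <- function(x, ...) {
  cat(sprintf("<st_map> %d time bins x %d voices (%g-%g Hz), kernel '%s'\n",
              nrow(x$magnitudes), ncol(x$magnitudes), min(x$freq_axis),
              max(x$freq_axis), x$kernel))
  invisible(x)
}
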