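#' Frequency-domain HRV indices
#'
#' Computes spectral power of the NN-interval tachogram in the standard
#' bands. The irregular tachogram (NN interval value at interval onset time)
#' is resampled to an even grid (default 4 Hz) by cubic-spline interpolation
#' (linear selectable), bridging exclusion gaps; the resampled series is
#' mean-centred, Hann-windowed, and a single full-record FFT periodogram is
#' computed with the normalization that makes the integral of the one-sided
#' power spectral density equal the (window-weighted) variance, so band
#' powers are in ms squared. Welch segment averaging is deliberately not
#' used: ULF power (below 0.003 Hz) needs full-record frequency resolution.
#'
#' Band edges are half-open `[lo, hi)` with ULF = (0, 0.003) Hz, VLF
#' 0.003-0.04, LF 0.04-0.15, HF 0.15-0.4; total power is the integral over
#' (0, 0.4] Hz.
#'
#' @param nn An `nn_series` from [extract_nn()]. Long records (>= 18 h of
#'   sinus data) are required for a meaningful ULF estimate; shorter series
#'   are computed as-is for diagnostic use.
#' @param resample_hz Even-grid resampling rate in Hz (default 4).
#' @param interp Interpolation used for resampling: `"spline"` (default,
#'   cubic) or `"linear"`.
#' @return Named list with `tp_ms2`, `ulf_ms2`, `vlf_ms2`, `lf_ms2`,
#'   `hf_ms2`.
#' @examples
#' tt <- seq(0, 3600 * 20, by = 0.8)
#' rr <- 800 + 50 * sin(2 * pi * 0.25 * tt)
#' b <- beat_series(tt, rep("N", length(tt)))
#' nn <- extract_nn(b)
#' nn$nn_ms <- 800 + 50 * sin(2 * pi * 0.25 * nn$onset_s)  # exact sinusoid
#' p <- hrv_frequency_domain(nn)
#' p$hf_ms2 / p$tp_ms2  # > 0.95
#' @export
hrv_frequency_domain <- function(nn, resample_hz = 4,
                                 interp = c("spline", "linear")) {
  stopifnot(inherits(nn, "nn_series"))
  interp <- match.arg(interp)
  t0 <- nn$onset_s
  if (length(unique(t0)) < 4L) stop("too few NN intervals for spectral analysis")
  fs <- resample_hz
  grid <- seq(min(t0), max(t0), by = 1 / fs)
  x <- if (interp == "spline") {
    stats::spline(t0, nn$nn_ms, xout = grid, method = "fmm")$y
  } else {
    stats::approx(t0, nn$nn_ms, xout = grid, rule = 2)$y
  }
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))  # Hann
  xc <- (x - mean(x)) * w
  X <- stats::fft(xc)
  # one-sided PSD, ms^2 per Hz; integral over f equals windowed variance
  kmax <- floor(n / 2)
  psd <- 2 * Mod(X[2:(kmax + 1)])^2 / (fs * sum(w^2))
  df <- fs / n
  f <- (1:kmax) * df

  band <- function(lo, hi, closed_hi = FALSE) {
    sel <- if (closed_hi) f >= lo & f <= hi else f >= lo & f < hi
    sum(psd[sel]) * df
  }
  list(tp_ms2 = band(df / 2, 0.4, closed_hi = TRUE),
       ulf_ms2 = band(df / 2, 0.003),
       vlf_ms2 = band(0.003, 0.04),
       lf_ms2 = band(0.04, 0.15),
       hf_ms2 = band(0.15, 0.4))
}
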