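#' Full HRV profile for one subject
#'
#' Runs the complete per-subject HRV chain: NN extraction with non-sinus
#' exclusion, the 18-hour minimum-duration rule, time-domain indices and
#' FFT band powers.
#'
#' @param beats A [beat_series()].
#' @param min_hours Minimum effective sinus duration (hours); recordings
#'   below it are rejected with an error unless `enforce_duration = FALSE`.
#' @param enforce_duration Apply the minimum-duration rule (default TRUE).
#' @param resample_hz,interp Passed to [hrv_frequency_domain()].
#' @return An object of class `hrv_profile`: a named list of the 12 indices
#'   (`sdnn_ms`, `sdann_ms`, `rmssd_ms`, `sdnn_index_ms`, `nn50_count`,
#'   `pnn50_pct`, `sdsd_ms`, `tp_ms2`, `ulf_ms2`, `vlf_ms2`, `lf_ms2`,
#'   `hf_ms2`) plus `effective_duration_h` and `n_nn`.
#' @seealso [hrv_composites()] for the cohort-level composite z-scores.
#' @export
hrv_profile <- function(beats, min_hours = 18, enforce_duration = TRUE,
                        resample_hz = 4, interp = "spline") {
  nn <- extract_nn(beats)
  if (enforce_duration && !check_duration(nn, min_hours))
    stop(sprintf("effective sinus duration %.2f h below the %g-h minimum",
                 attr(nn, "effective_duration_h"), min_hours))
  td <- hrv_time_domain(nn)
  fd <- hrv_frequency_domain(nn, resample_hz = resample_hz, interp = interp)
  out <- c(td, fd,
           list(effective_duration_h = attr(nn, "effective_duration_h"),
                n_nn = nrow(nn)))
  class(out) <- "hrv_profile"
  out
}

#' @export
print.hrv_profile <- function(x, ...) {
  cat("24-h HRV profile (", sprintf("%.1f", x$effective_duration_h),
      " h sinus data, ", x$n_nn, " NN intervals)\n", sep = "")
  cat(sprintf("  time domain:  SDNN %.1f  SDANN %.1f  RMSSD %.1f  SDNNi %.1f ms; pNN50 %.2f%%\n",
              x$sdnn_ms, x$sdann_ms, x$rmssd_ms, x$sdnn_index_ms, x$pnn50_pct))
  cat(sprintf("  freq domain:  TP %.0f  ULF %.0f  VLF %.0f  LF %.0f  HF %.0f ms^2\n",
              x$tp_ms2, x$ulf_ms2, x$vlf_ms2, x$lf_ms2, x$hf_ms2))
  invisible(x)
}

# columns entering each composite
.hrv_time_cols <- c("sdnn_ms", "rmssd_ms", "sdann_ms", "sdnn_index_ms", "pnn50_pct")
.hrv_freq_cols <- c("tp_ms2", "ulf_ms2", "vlf_ms2", "lf_ms2", "hf_ms2")

# z-score a column against the analysis sample; error on zero variance
.zscore <- function(x, what = "variable") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop(sprintf("zero variance in %s across the cohort: composite undefined", what))
  (x - mean(x)) / s
}

#' Cohort-level HRV composite z-scores
#'
#' Each HRV index is z-scored against the analysis sample, and the composite
#' is the mean of the five stated index z-scores per domain: time domain
#' (SDNN + RMSSD + SDANN + SDNN index + pNN50)/5; frequency domain
#' (TP + ULF + VLF + LF + HF)/5. Indices enter as raw z-scores (no
#' transformation of skewed indices).
#'
#' @param profiles A data frame with one row per subject and the index
#'   columns named as in [hrv_profile()] (e.g. built with
#'   `do.call(rbind, lapply(profs, as.data.frame))`).
#' @return `profiles` with added columns `hrv_time_z` and `hrv_freq_z`.
#' @export
hrv_composites <- function(profiles) {
  profiles <- as.data.frame(profiles)
  need <- c(.hrv_time_cols, .hrv_freq_cols)
  miss <- setdiff(need, names(profiles))
  if (length(miss)) stop("missing HRV index columns: ", paste(miss, collapse = ", "))
  if (nrow(profiles) < 2L) stop("need at least two subjects")
  zt <- sapply(.hrv_time_cols, function(cl) .zscore(profiles[[cl]], cl))
  zf <- sapply(.hrv_freq_cols, function(cl) .zscore(profiles[[cl]], cl))
  profiles$hrv_time_z <- rowMeans(zt)
  profiles$hrv_freq_z <- rowMeans(zf)
  profiles
}
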