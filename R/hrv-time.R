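#' Time-domain HRV indices
#'
#' Computes the standard time-domain heart rate variability measures from an
#' NN-interval series:
#' \describe{
#'   \item{SDNN}{sample SD of all NN intervals (ms).}
#'   \item{SDANN}{sample SD of the mean NN interval per 5-minute segment (ms).}
#'   \item{SDNN index}{mean of the per-segment sample SDs (ms); segments with
#'     fewer than two intervals contribute no SD.}
#'   \item{RMSSD}{root mean square of successive NN differences (ms).}
#'   \item{NN50}{count of successive pairs differing by more than 50 ms.}
#'   \item{pNN50}{100 * NN50 / total number of NN intervals (\%).}
#'   \item{SDSD}{reported equal to RMSSD.}
#' }
#' All SDs use the sample (n-1) denominator. Successive pairs are taken only
#' within contiguous sinus runs, never across an exclusion gap. NN50 uses the
#' strict inequality |difference| > 50 ms. The pNN50 denominator is the total
#' NN interval count (not the number of successive pairs).
#'
#' @param nn An `nn_series` from [extract_nn()].
#' @return A named list with elements `sdnn_ms`, `sdann_ms`, `rmssd_ms`,
#'   `sdnn_index_ms`, `nn50_count`, `pnn50_pct`, `sdsd_ms`. `sdann_ms` and
#'   `sdnn_index_ms` are `NA` when fewer than two segments are available.
#' @examples
#' b <- beat_series(cumsum(c(0, rep(0.8, 10))), rep("N", 11))
#' hrv_time_domain(extract_nn(b))
#' @export
hrv_time_domain <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  x <- nn$nn_ms
  if (length(x) < 2L) stop("need at least two NN intervals")
  sdnn <- stats::sd(x)

  seg_means <- tapply(x, nn$segment, mean)
  if (length(seg_means) >= 2L) {
    sdann <- stats::sd(seg_means)
    seg_sizes <- tapply(x, nn$segment, length)
    seg_sds <- tapply(x, nn$segment, stats::sd)[seg_sizes >= 2L]
    sdnn_index <- if (length(seg_sds)) mean(seg_sds) else NA_real_
  } else {
    sdann <- NA_real_
    sdnn_index <- NA_real_
  }

  # successive differences within contiguous runs only
  same_run <- diff(nn$run) == 0L
  d <- diff(x)[same_run]
  if (length(d)) {
    rmssd <- sqrt(mean(d^2))
    nn50 <- sum(abs(d) > 50)
  } else {
    rmssd <- NA_real_
    nn50 <- 0L
  }
  pnn50 <- 100 * nn50 / length(x)

  list(sdnn_ms = sdnn, sdann_ms = sdann, rmssd_ms = rmssd,
       sdnn_index_ms = sdnn_index, nn50_count = as.integer(nn50),
       pnn50_pct = pnn50, sdsd_ms = rmssd)
}
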