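#' Construct a labelled beat series
#'
#' A beat series is the raw input to all HRV computation: one record per
#' detected heartbeat, giving the beat time in seconds from the start of the
#' recording and a label classifying the beat as sinus (`"N"`), ectopic
#' (`"E"`) or artifact (`"A"`). QRS detection itself is out of scope; the
#' pipeline starts at labelled beats.
#'
#' @param beat_time_s Numeric vector of beat times in seconds, strictly
#'   increasing.
#' @param label Character vector of beat labels, one of `"N"`, `"E"`, `"A"`.
#' @param duration_h Recording duration in hours. Defaults to the last beat
#'   time; must be at least the last beat time.
#' @return An object of class `beat_series`: a data frame with columns
#'   `beat_time_s` and `label`, and attribute `duration_h`.
#' @examples
#' b <- beat_series(c(0, 0.8, 1.6), c("N", "N", "N"))
#' extract_nn(b)
#' @export
beat_series <- function(beat_time_s, label, duration_h = NULL) {
  beat_time_s <- as.numeric(beat_time_s)
  label <- as.character(label)
  if (length(beat_time_s) != length(label))
    stop("beat_time_s and label must have the same length")
  if (length(beat_time_s) < 1L) stop("empty beat series")
  if (any(diff(beat_time_s) <= 0)) stop("beat times must be strictly increasing")
  if (!all(label %in% c("N", "E", "A")))
    stop("labels must be one of 'N' (sinus), 'E' (ectopic), 'A' (artifact)")
  if (is.null(duration_h)) duration_h <- beat_time_s[length(beat_time_s)] / 3600
  duration_h <- as.numeric(duration_h)
  if (duration_h * 3600 < beat_time_s[length(beat_time_s)] - 1e-9)
    stop("duration_h is shorter than the last beat time")
  out <- data.frame(beat_time_s = beat_time_s, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "duration_h") <- duration_h
  class(out) <- c("beat_series", "data.frame")
  out
}

#' Read a beat file
#'
#' Reads a whitespace-delimited text file with two columns: beat time in
#' seconds and beat label (N/E/A), as written by [write_beats()] and by the
#' signal-level cohort generator.
#'
#' @param path Path to the beat file.
#' @param duration_h Optional recording duration in hours.
#' @return A [beat_series()].
#' @export
read_beats <- function(path, duration_h = NULL) {
  d <- utils::read.table(path, header = FALSE, col.names = c("beat_time_s", "label"),
                         colClasses = c("numeric", "character"))
  beat_series(d$beat_time_s, d$label, duration_h = duration_h)
}

#' @rdname read_beats
#' @param beats A [beat_series()] to write.
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  utils::write.table(data.frame(beats$beat_time_s, beats$label), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract normal-to-normal (NN) intervals from a labelled beat series
#'
#' An interbeat interval is retained as an NN interval only when both of the
#' beats delimiting it are sinus beats; every interval adjacent to an ectopic
#' or artifact beat is dropped. Retained intervals that are separated by a
#' dropped interval belong to different contiguous runs: successive-difference
#' statistics (RMSSD, NN50, pNN50, SDSD) never span an exclusion gap.
#'
#' @param beats A [beat_series()].
#' @param segment_s Length of the analysis segments used for SDANN and the
#'   SDNN index, in seconds (default 300 = 5 minutes). Segments are
#'   consecutive bins of the recording clock.
#' @return An object of class `nn_series`: a data frame with columns
#'   `onset_s` (time of the first beat of the interval), `nn_ms` (interval in
#'   milliseconds), `segment` (integer 5-minute bin index) and `run` (integer
#'   id of the contiguous sinus run), with attribute `effective_duration_h`,
#'   the summed duration of retained NN intervals in hours.
#' @examples
#' b <- beat_series(c(0, 0.8, 1.6, 2.4, 3.2), c("N", "N", "A", "N", "N"))
#' extract_nn(b)$nn_ms  # 800, 800; the intervals touching the artifact drop
#' @export
extract_nn <- function(beats, segment_s = 300) {
  stopifnot(inherits(beats, "beat_series"))
  n <- nrow(beats)
  if (n < 2L) stop("need at least two beats")
  ok <- beats$label[-n] == "N" & beats$label[-1L] == "N"
  if (!any(ok)) stop("no NN intervals: recording unusable")
  onset <- beats$beat_time_s[-n][ok]
  # nanosecond rounding removes floating-point dust from reconstructed beat
  # times, which matters at the strict |delta| > 50 ms NN50 boundary
  nn_ms <- round(diff(beats$beat_time_s)[ok] * 1e9) / 1e6
  idx <- which(ok)
  new_run <- c(TRUE, diff(idx) != 1L)
  run <- cumsum(new_run)
  out <- data.frame(onset_s = onset, nn_ms = nn_ms,
                    segment = as.integer(floor(onset / segment_s)),
                    run = as.integer(run))
  attr(out, "effective_duration_h") <- sum(nn_ms) / 3.6e6
  attr(out, "duration_h") <- attr(beats, "duration_h")
  class(out) <- c("nn_series", "data.frame")
  out
}

#' Minimum-duration eligibility for HRV analysis
#'
#' A recording qualifies for HRV analysis only when at least `min_hours`
#' (default 18 h) of sinus data remain after non-sinus exclusion. The
#' boundary is inclusive: exactly 18 h passes.
#'
#' @param nn An `nn_series` from [extract_nn()].
#' @param min_hours Minimum effective sinus duration in hours.
#' @return `TRUE` if the recording qualifies, `FALSE` otherwise.
#' @export
check_duration <- function(nn, min_hours = 18) {
  stopifnot(inherits(nn, "nn_series"))
  attr(nn, "effective_duration_h") >= min_hours
}
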