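# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive quantities with naive loops so
# they stay independent of the package's implementation paths.

# beats at exact cumulative times from a vector of NN intervals in ms
beats_from_nn <- function(nn_ms, labels = NULL) {
  tt <- cumsum(c(0, nn_ms)) / 1000
  if (is.null(labels)) labels <- rep("N", length(tt))
  beat_series(tt, labels)
}

# brute-force NN extraction: keep interval i iff beats i and i+1 are sinus;
# returns list of contiguous runs of intervals
brute_nn_runs <- function(times_s, labels) {
  runs <- list()
  cur <- numeric(0)
  for (i in seq_len(length(times_s) - 1)) {
    if (labels[i] == "N" && labels[i + 1] == "N") {
      cur <- c(cur, (times_s[i + 1] - times_s[i]) * 1000)
    } else if (length(cur)) {
      runs[[length(runs) + 1]] <- cur
      cur <- numeric(0)
    }
  }
  if (length(cur)) runs[[length(runs) + 1]] <- cur
  runs
}

brute_time_domain <- function(runs) {
  x <- unlist(runs)
  d <- unlist(lapply(runs, function(r) if (length(r) > 1) diff(r) else numeric(0)))
  list(sdnn = stats::sd(x),
       rmssd = if (length(d)) sqrt(mean(d^2)) else NA_real_,
       nn50 = sum(abs(d) > 50),
       pnn50 = 100 * sum(abs(d) > 50) / length(x))
}

# a long sinus recording whose NN intervals follow rr_fun(t) evaluated at
# the (iteratively consistent) beat times
sinusoid_beats <- function(duration_h, rr_fun, mean_rr_s = 0.8) {
  n <- ceiling(duration_h * 3600 / mean_rr_s * 1.3)
  tt <- cumsum(rep(mean_rr_s, n))
  for (i in 1:3) {
    rr <- rr_fun(c(0, tt[-n]))
    tt <- cumsum(rr)
  }
  tt <- tt[tt <= duration_h * 3600]
  beat_series(tt, rep("N", length(tt)))
}

# standard 7-point glucose curve used in OGTT fixtures
toy_glucose <- function() c(5.2, 7.0, 8.2, 8.0, 7.2, 6.0, 5.4)

toy_ogtt <- function(glucose = toy_glucose(),
                     cpeptide = c(600, 1100, 1500, 1600, 1550, 1300, 1100),
                     insulin = c(60, 140, 210, 220, 200, 150, 110)) {
  ogtt_record(c(0, 15, 30, 45, 60, 90, 120), glucose, cpeptide, insulin)
}

# flat-potentiation beta-cell truth (the regime where round-trip recovery
# is identified; see the methods vignette)
flat_truth <- function(latent = 0) {
  tr <- hrvbeta:::.betacell_truth(latent)
  tr$potentiation_ratio <- 1
  tr
}
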