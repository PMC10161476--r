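test_that("worked five-interval series reproduces hand-computed indices", {
  nn <- extract_nn(beats_from_nn(c(800, 810, 790, 850, 800)))
  td <- hrv_time_domain(nn)
  expect_equal(td$sdnn_ms, sqrt(550), tolerance = 1e-9)
  expect_equal(td$rmssd_ms, sqrt(1650), tolerance = 1e-9)
  expect_equal(td$nn50_count, 1L)        # only |60| exceeds 50 ms strictly
  expect_equal(td$pnn50_pct, 20)         # denominator is all 5 NN intervals
  expect_identical(td$sdsd_ms, td$rmssd_ms)
})

test_that("constant series yields zero variability", {
  td <- hrv_time_domain(extract_nn(beats_from_nn(rep(800, 2000))))
  expect_equal(td$sdnn_ms, 0)
  expect_equal(td$rmssd_ms, 0)
  expect_equal(td$nn50_count, 0L)
  expect_equal(td$pnn50_pct, 0)
})

test_that("SDANN matches the sample SD of 5-minute segment means", {
  # two segments with means 800 and 900 ms
  nn <- c(rep(800, 375), rep(900, 333))
  td <- hrv_time_domain(extract_nn(beats_from_nn(nn)))
  expect_equal(td$sdann_ms, sqrt((-50)^2 + 50^2), tolerance = 1e-6)
  # single segment: SDANN undefined
  td1 <- hrv_time_domain(extract_nn(beats_from_nn(rep(800, 100))))
  expect_true(is.na(td1$sdann_ms))
})

test_that("successive differences never span an exclusion gap", {
  # two runs: [800, 900] and [700, 820]; the 900 -> 700 jump must not count
  lab <- c("N", "N", "N", "A", "N", "N", "N")
  nn <- extract_nn(beat_series(cumsum(c(0, 0.8, 0.9, 0.5, 0.6, 0.7, 0.82)), lab))
  td <- hrv_time_domain(nn)
  d <- c(100, 120)  # within-run differences only
  expect_equal(td$rmssd_ms, sqrt(mean(d^2)), tolerance = 1e-6)
  expect_equal(td$nn50_count, 2L)
})

test_that("time-domain metrics are invariant to time translation and level shift", {
  set.seed(11)
  nn <- 800 + round(rnorm(600, 0, 40))
  b1 <- beats_from_nn(nn)
  b2 <- beat_series(b1$beat_time_s + 1234.5, b1$label)
  expect_equal(hrv_time_domain(extract_nn(b1))[c("sdnn_ms", "rmssd_ms", "nn50_count")],
               hrv_time_domain(extract_nn(b2))[c("sdnn_ms", "rmssd_ms", "nn50_count")])
  # adding a constant to all NN intervals leaves SDNN, RMSSD, NN50 unchanged
  b3 <- beats_from_nn(nn + 150)
  t1 <- hrv_time_domain(extract_nn(b1)); t3 <- hrv_time_domain(extract_nn(b3))
  expect_equal(t1$sdnn_ms, t3$sdnn_ms, tolerance = 1e-9)
  expect_equal(t1$rmssd_ms, t3$rmssd_ms, tolerance = 1e-9)
  expect_equal(t1$nn50_count, t3$nn50_count)
})

test_that("package indices match a brute-force oracle on random labelled series", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(300:800, 1)
    nn <- 800 + rnorm(n, 0, 45)
    lab <- sample(c("N", "E", "A"), n + 1, replace = TRUE, prob = c(0.92, 0.05, 0.03))
    tt <- cumsum(c(0, nn)) / 1000
    if (sum(lab[-length(lab)] == "N" & lab[-1] == "N") < 10) next
    b <- beat_series(tt, lab)
    got <- hrv_time_domain(extract_nn(b))
    want <- brute_time_domain(brute_nn_runs(tt, lab))
    expect_equal(got$sdnn_ms, want$sdnn, tolerance = 1e-9)
    expect_equal(got$rmssd_ms, want$rmssd, tolerance = 1e-9)
    expect_equal(got$nn50_count, want$nn50)
    expect_equal(got$pnn50_pct, want$pnn50, tolerance = 1e-9)
  }
})
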