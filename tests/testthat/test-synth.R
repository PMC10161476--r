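test_that("covariate marginals match the cohort description", {
  d <- draw_covariates(100000, seed = 2)
  expect_lt(abs(mean(d$age) - 60), 0.1)
  expect_lt(abs(sd(d$age) - 8), 0.1)
  expect_true(all(d$age >= 40 & d$age <= 75))
  expect_lt(abs(mean(d$sex == "M") - 0.52), 0.01)
  expect_lt(max(abs(unname(prop.table(table(d$gms))) - c(0.60, 0.16, 0.24))),
            0.01)
})

test_that("a 2007-subject draw carries about 24% type 2 diabetes", {
  d <- draw_covariates(2007, seed = 7)
  expect_lt(abs(sum(d$gms == "T2D") / 2007 - 476 / 2007), 0.03)
  expect_identical(draw_covariates(2007, seed = 7), d)
})

test_that("beat synthesis honours its modulation contract", {
  # all modulation off -> constant RR -> zero SDNN
  b0 <- synthesize_beat_series(0, duration_h = 1, modulation = list(
    circadian = 0, vlf = 0, lf = 0, hf = 0, white = 0), seed = 1)
  td <- hrv_time_domain(extract_nn(b0))
  expect_equal(td$sdnn_ms, 0, tolerance = 1e-9)
  expect_true(all(diff(b0$beat_time_s) > 0))

  # HF-only modulation concentrates power in the HF band
  bh <- synthesize_beat_series(0, duration_h = 19, modulation = list(
    circadian = 0, vlf = 0, lf = 0, hf = 40, white = 0),
    ectopic_fraction = 0, artifact_fraction = 0, seed = 2)
  p <- hrv_frequency_domain(extract_nn(bh))
  expect_gt(p$hf_ms2 / p$tp_ms2, 0.9)

  # labelled non-sinus fraction matches the request
  b5 <- synthesize_beat_series(0, duration_h = 6, ectopic_fraction = 0.05,
                               artifact_fraction = 0, seed = 3)
  expect_lt(abs(mean(b5$label == "E") - 0.05), 0.005)

  expect_error(synthesize_beat_series(0, duration_h = -1), "duration")
  expect_error(synthesize_beat_series(0, mean_rr_ms = 100), "mean_rr_ms")
  expect_identical(synthesize_beat_series(0.5, duration_h = 2, seed = 9),
                   synthesize_beat_series(0.5, duration_h = 2, seed = 9))
})

test_that("OGTT synthesis is deterministic and respects steady state", {
  kin <- cpeptide_kinetics(60, "M", 26, "NGM")
  tr <- flat_truth(0)
  r1 <- synthesize_ogtt(tr, "NGM", kin, noise_cv = 0.04, seed = 4)
  r2 <- synthesize_ogtt(tr, "NGM", kin, noise_cv = 0.04, seed = 4)
  expect_identical(r1, r2)
  # zero-excursion template, no noise -> flat C-peptide at basal
  r0 <- synthesize_ogtt(tr, "NGM", kin, noise_cv = 0,
                        glucose_template = rep(5.2, 7))
  expect_equal(diff(range(r0$cpeptide_pmol_l)), 0, tolerance = 1e-9)
  # prediabetes template produces the highest insulin excursion
  exc <- sapply(c("NGM", "prediabetes", "T2D"), function(g) {
    r <- synthesize_ogtt(hrvbeta:::.betacell_truth(0), g,
                         cpeptide_kinetics(60, "M", 27, g), noise_cv = 0, seed = 1)
    max(r$insulin_pmol_l) - r$insulin_pmol_l[1]
  })
  expect_true(exc["prediabetes"] > exc["NGM"] && exc["prediabetes"] > exc["T2D"])
})

test_that("noise-free synthetic records round-trip through the model fit", {
  kin <- cpeptide_kinetics(58, "F", 24, "NGM")
  tr <- flat_truth(0.5)
  rec <- synthesize_ogtt(tr, "NGM", kin, noise_cv = 0)
  fit <- fit_betacell(rec, kin, measurement_cv = 0)
  expect_lt(abs(coef(fit)[["glucose_sensitivity"]] - tr$glucose_sensitivity),
            0.05 * tr$glucose_sensitivity)
})

test_that("per-subject substreams make subjects independent of cohort size", {
  s_small <- simulate_cohort(8, seed = 11, mode = "signals", duration_h = 0.5)
  s_big <- simulate_cohort(12, seed = 11, mode = "signals", duration_h = 0.5)
  expect_identical(s_small$beats[[2]], s_big$beats[[2]])
  expect_identical(s_small$ogtt[[7]]$cpeptide_pmol_l,
                   s_big$ogtt[[7]]$cpeptide_pmol_l)
})

test_that("signal mode writes the documented file layout", {
  out <- file.path(tempdir(), "simout")
  sim <- simulate_cohort(7, seed = 1, mode = "signals", duration_h = 0.2,
                         out_dir = out)
  expect_true(file.exists(file.path(out, "covariates.csv")))
  expect_true(file.exists(file.path(out, "scores.csv")))
  expect_true(file.exists(file.path(out, "beats", "S00001.txt")))
  expect_true(file.exists(file.path(out, "ogtt", "S00002.csv")))
  b <- read_beats(file.path(out, "beats", "S00001.txt"))
  expect_s3_class(b, "beat_series")
  unlink(out, recursive = TRUE)
})
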