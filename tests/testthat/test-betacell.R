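kin0 <- cpeptide_kinetics(60, "M", 26, "NGM")
glu0 <- data.frame(t_min = c(0, 15, 30, 45, 60, 90, 120),
                   glucose_mmol_l = toy_glucose())

test_that("kinetic constants are deterministic, positive and size-monotone", {
  k1 <- cpeptide_kinetics(60, "M", 26, "NGM")
  k2 <- cpeptide_kinetics(60, "M", 26, "NGM")
  expect_identical(unclass(k1), unclass(k2))
  expect_true(all(c(k1$k01, k1$k12, k1$k21, k1$v_d) > 0))
  big <- cpeptide_kinetics(60, "M", 26, "NGM", height_cm = 190, weight_kg = 100)
  sml <- cpeptide_kinetics(60, "M", 26, "NGM", height_cm = 160, weight_kg = 55)
  expect_gt(big$v_d, sml$v_d)
  expect_error(cpeptide_kinetics(150, "M", 26, "NGM"), "range")
  # class-specific half-lives differ
  expect_false(isTRUE(all.equal(cpeptide_kinetics(60, "M", 26, "T2D")$a, k1$a)))
})

test_that("flat glucose at basal leaves C-peptide at steady state", {
  gflat <- data.frame(t_min = c(0, 15, 30, 45, 60, 90, 120),
                      glucose_mmol_l = rep(5, 7))
  sim <- forward_simulate_ogtt(list(glucose_sensitivity = 100,
                                    rate_sensitivity = 0,
                                    basal_secretion = 100), gflat, kin0)
  expect_equal(diff(range(sim$cpeptide_pmol_l)), 0, tolerance = 1e-9)
  # steady state: concentration = secretion / (k01 * Vd) (whole-body units)
  expect_equal(sim$cpeptide_pmol_l[1],
               100 * kin0$bsa_m2 / (kin0$k01 * kin0$v_d), tolerance = 1e-9)
})

test_that("incremental secretion is linear in the dose-response slope", {
  base <- list(rate_sensitivity = 0, basal_secretion = 100)
  s1 <- forward_simulate_ogtt(c(base, glucose_sensitivity = 50), glu0, kin0)
  s2 <- forward_simulate_ogtt(c(base, glucose_sensitivity = 100), glu0, kin0)
  inc1 <- sum(attr(s1, "isr") - 100)
  inc2 <- sum(attr(s2, "isr") - 100)
  expect_equal(inc2 / inc1, 2, tolerance = 1e-9)
})

test_that("with no rate term and flat potentiation, ISR tracks the dose-response", {
  sim <- forward_simulate_ogtt(list(glucose_sensitivity = 80, rate_sensitivity = 0,
                                    basal_secretion = 100), glu0, kin0)
  G <- approx(glu0$t_min, glu0$glucose_mmol_l, xout = attr(sim, "t_grid"))$y
  expect_equal(attr(sim, "isr"), pmax(0, 100 + 80 * (G - G[1])), tolerance = 1e-12)
})

test_that("deconvolution recovers steady state and smooth secretion", {
  # constant C-peptide -> flat ISR equal to clearance * concentration
  tmin <- seq(0, 120, 5)
  dec <- deconvolve_isr(tmin, rep(600, length(tmin)), kin0, lambda = 100)
  expect_equal(dec$isr_pmol_min_m2,
               rep(kin0$k01 * kin0$v_d * 600 / kin0$bsa_m2, nrow(dec)),
               tolerance = 1e-6)
  # round trip on a smooth secretion curve, noise-free dense sampling
  sim <- forward_simulate_ogtt(list(glucose_sensitivity = 90, rate_sensitivity = 300,
                                    basal_secretion = 90), glu0, kin0,
                               t_out = seq(0, 120, 5))
  dec2 <- deconvolve_isr(sim$t_min, sim$cpeptide_pmol_l, kin0, lambda = 100)
  isr_true <- approx(attr(sim, "t_grid"), attr(sim, "isr"), xout = dec2$t_min)$y
  rmse <- sqrt(mean((dec2$isr_pmol_min_m2 - isr_true)^2))
  expect_lt(rmse / mean(isr_true), 0.05)
  # strong regularization tends to a constant rate
  dec3 <- deconvolve_isr(sim$t_min, sim$cpeptide_pmol_l, kin0, lambda = 1e8)
  expect_lt(sd(dec3$isr_pmol_min_m2) / mean(dec3$isr_pmol_min_m2), 0.01)
  expect_true(all(dec2$isr_pmol_min_m2 >= 0))
})

test_that("noise-free flat-potentiation records are recovered essentially exactly", {
  sim <- forward_simulate_ogtt(list(glucose_sensitivity = 100,
                                    rate_sensitivity = 600,
                                    basal_secretion = 90), glu0, kin0)
  fit <- fit_betacell(sim, kin0, measurement_cv = 0)
  expect_equal(coef(fit)[["glucose_sensitivity"]], 100, tolerance = 0.05)
  expect_equal(coef(fit)[["potentiation_ratio"]], 1, tolerance = 0.05)
  expect_lt(abs(coef(fit)[["rate_sensitivity"]] - 600), 0.05 * 724)
  # null rate sensitivity is recovered as null
  sim0 <- forward_simulate_ogtt(list(glucose_sensitivity = 100,
                                     rate_sensitivity = 0,
                                     basal_secretion = 90), glu0, kin0)
  fit0 <- fit_betacell(sim0, kin0, measurement_cv = 0)
  expect_lt(abs(coef(fit0)[["rate_sensitivity"]]), 0.05 * 724)
})

test_that("fit methods behave like a standard model object", {
  sim <- forward_simulate_ogtt(list(glucose_sensitivity = 90, rate_sensitivity = 500,
                                    basal_secretion = 90), glu0, kin0)
  fit <- fit_betacell(sim, kin0, measurement_cv = 0)
  expect_s3_class(fit, "betacell_fit")
  expect_named(coef(fit), c("glucose_sensitivity", "rate_sensitivity",
                            "basal_secretion", "potentiation_ratio"))
  expect_length(fitted(fit), 7)
  expect_equal(fitted(fit) + residuals(fit), sim$cpeptide_pmol_l)
  expect_equal(predict(fit, newdata = data.frame(t_min = sim$t_min)),
               fitted(fit), tolerance = 0.02)
  expect_output(print(fit), "glucose sensitivity")
})

test_that("parameter recovery holds across noisy synthetic subjects", {
  # 4% assay CV, flat-potentiation truths (the identified regime)
  set.seed(42)
  errs <- vapply(1:30, function(k) {
    tr <- flat_truth(rnorm(1))
    gms <- sample(c("NGM", "prediabetes", "T2D"), 1, prob = c(0.6, 0.16, 0.24))
    kin <- cpeptide_kinetics(60, "M", 27, gms)
    rec <- synthesize_ogtt(tr, gms, kin, noise_cv = 0.04, seed = 4000 + k)
    f <- fit_betacell(rec, kin)
    (coef(f)[["glucose_sensitivity"]] - tr$glucose_sensitivity) /
      tr$glucose_sensitivity
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.15)
  expect_gt(stats::wilcox.test(errs)$p.value, 0.05)
})
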