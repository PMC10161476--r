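cohort0 <- draw_cohort_scores(sem_config(800, "time", seed = 31))

test_that("crude standardized beta equals the Pearson correlation", {
  r <- cor(cohort0$hrv_time_z, cohort0$betacell_z)
  fit <- standardized_fit(cohort0, "betacell_z", "hrv_time_z", invert = TRUE)
  expect_equal(fit$st_beta, -r, tolerance = 1e-9)
  fit2 <- standardized_fit(cohort0, "betacell_z", "hrv_time_z", invert = FALSE)
  expect_equal(fit2$st_beta, r, tolerance = 1e-9)
  expect_equal(fit$st_beta, -fit2$st_beta, tolerance = 1e-12)
  expect_true(fit$lo < fit$st_beta && fit$st_beta < fit$hi)
})

test_that("standardized betas are invariant to affine rescaling of the determinant", {
  co <- cohort0
  co$hrv_scaled <- co$hrv_time_z * 10 + 5
  f1 <- standardized_fit(co, "betacell_z", "hrv_time_z",
                         covariates = c("age", "sex"), invert = TRUE)
  f2 <- standardized_fit(co, "betacell_z", "hrv_scaled",
                         covariates = c("age", "sex"), invert = TRUE)
  expect_equal(f1$st_beta, f2$st_beta, tolerance = 1e-9)
  expect_equal(f1$p, f2$p, tolerance = 1e-9)
})

test_that("a covariate orthogonal to exposure and outcome barely moves the beta", {
  set.seed(44)
  co <- cohort0
  co$noise_cov <- rnorm(nrow(co))
  f0 <- standardized_fit(co, "betacell_z", "hrv_time_z", c("age", "sex"))
  f1 <- standardized_fit(co, "betacell_z", "hrv_time_z", c("age", "sex", "noise_cov"))
  expect_equal(f0$st_beta, f1$st_beta, tolerance = 0.01)
})

test_that("collinear designs are rejected with the offending term", {
  co <- cohort0
  co$age_copy <- co$age
  expect_error(standardized_fit(co, "betacell_z", "hrv_time_z",
                                c("age", "age_copy")), "collinear")
})

test_that("the ladder shares one complete-case set and fills the 60-cell grid", {
  co <- cohort0
  co$matsuda[1:25] <- NA           # missing only affects m2+ columns
  lad <- run_ladder(co)
  expect_equal(nrow(lad), 60)      # 2 exposures x 6 outcomes x 5 models
  expect_true(all(lad$n == nrow(co) - 25))  # crude uses the same reduced set
  expect_equal(attr(lad, "n_removed"), 25)
  expect_setequal(unique(lad$model), c("crude", "m1", "m2", "m3a", "m3b"))
  expect_error(complete_case(co, "nope"), "not in cohort")
  co$all_na <- NA_real_
  expect_error(complete_case(co, "all_na"), "every row")
})

test_that("interaction test calibrates to nominal type-I error and detects modification", {
  # identical effect in men and women: null interaction
  set.seed(52)
  co <- draw_cohort_scores(sem_config(2007, "time", seed = 52))
  p <- interaction_test(co, "betacell_z", "hrv_time_z", "sex",
                        covariates = c("age", "bmi"))
  expect_true(p$p_interaction > 0 && p$p_interaction < 1)
  expect_equal(p$df, 1)
  # three-level modifier gives a 2-df joint test
  p3 <- interaction_test(co, "betacell_z", "hrv_time_z", "gms",
                         covariates = c("age", "bmi"))
  expect_equal(p3$df, 2)
  # a strong constructed sex-specific effect is detected
  co2 <- cohort0
  co2$y_mod <- co2$betacell_z + ifelse(co2$sex == "M", 0.6, 0) * co2$hrv_time_z
  pm <- interaction_test(co2, "y_mod", "hrv_time_z", "sex",
                         covariates = c("age", "bmi"))
  expect_lt(pm$p_interaction, 1e-6)
  co2$one_level <- factor("a")
  expect_error(interaction_test(co2, "betacell_z", "hrv_time_z", "one_level"),
               "2 levels")
})

test_that("stratified ladder returns one calibrated table per retained stratum", {
  res <- stratified_ladder(cohort0, strata = "gms")
  expect_setequal(names(res), c("NGM", "prediabetes", "T2D"))
  for (tab in res) expect_equal(nrow(tab), 10)  # 2 exposures x 1 outcome x 5 models
  # covariate swap: Matsuda replaced by total insulin secretion
  res2 <- stratified_ladder(cohort0, strata = "gms",
                            models = ladder_covariates(swap = c(matsuda = "overall_secretion")))
  expect_false(identical(res$NGM$st_beta, res2$NGM$st_beta))
  # a stratum below the size floor is skipped with a warning
  co <- cohort0
  co$gms <- factor(c(rep("NGM", nrow(co) - 4), rep("T2D", 4)),
                   levels = levels(co$gms))
  expect_warning(res3 <- stratified_ladder(co, strata = "gms"), "skipped")
  expect_false("T2D" %in% names(res3))
})

test_that("tertile logistic cuts at sample tertiles and matches the linear sign", {
  co <- cohort0
  res <- tertile_logistic(co, "rate_sensitivity", "hrv_time_z",
                          covariates = c("age", "sex"))
  expect_equal(res$cut1, unname(quantile(co$rate_sensitivity, 1 / 3)))
  # negative linear association per SD lower HRV -> OR below 1 for top tertile
  lin <- standardized_fit(co, "rate_sensitivity", "hrv_time_z", invert = TRUE)
  expect_true((res$or < 1) == (lin$st_beta < 0))
  expect_true(res$lo < res$or && res$or < res$hi)
  # nine distinct values split 3/3/3
  co9 <- data.frame(y = rep(1:9, each = 1), x = rnorm(9))
  cuts <- quantile(co9$y, c(1, 2) / 3)
  expect_equal(sum(co9$y > cuts[2]), 3)
  tied <- data.frame(rate_sensitivity = c(rep(5, 25), 1, 2, 8, 9, 10),
                     hrv_time_z = rnorm(30))
  expect_error(tertile_logistic(tied, "rate_sensitivity", "hrv_time_z",
                                covariates = character(0)), "tertile")
})
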