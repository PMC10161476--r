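# Standardized-beta covariate-adjustment ladder and related analyses.

#' Cumulative covariate ladder definition
#'
#' The five adjustment models: crude (no covariates); model 1 adds age, sex
#' and educational status; model 2 adds the Matsuda index; model 3A adds
#' total/HDL cholesterol ratio, lipid-modifying medication, BMI, smoking and
#' alcohol status; model 3B adds office systolic blood pressure and
#' antihypertensive medication.
#'
#' @param swap Optional named character vector renaming covariates, e.g.
#'   `c(matsuda = "overall_secretion")` for the sensitivity re-analysis that
#'   replaces the Matsuda index by total insulin secretion.
#' @return Named list of character vectors of covariate column names.
#' @export
ladder_covariates <- function(swap = NULL) {
  sets <- list(
    crude = character(0),
    m1 = c("age", "sex", "education"),
    m2 = c("age", "sex", "education", "matsuda"),
    m3a = c("age", "sex", "education", "matsuda", "chol_hdl_ratio",
            "lipid_med", "bmi", "smoking", "alcohol"),
    m3b = c("age", "sex", "education", "matsuda", "chol_hdl_ratio",
            "lipid_med", "bmi", "smoking", "alcohol", "office_sbp",
            "antihyp_med"))
  if (!is.null(swap)) {
    sets <- lapply(sets, function(s) {
      for (nm in names(swap)) s[s == nm] <- swap[[nm]]
      s
    })
  }
  sets
}

#' Restrict a cohort to complete cases
#'
#' Removes every row with a missing value in any of the listed columns; the
#' same complete-case set is used for every model of the ladder so the
#' models are comparable.
#'
#' @param cohort Data frame.
#' @param columns Character vector of column names.
#' @return The filtered data frame, with attribute `n_removed`.
#' @export
complete_case <- function(cohort, columns) {
  miss <- setdiff(columns, names(cohort))
  if (length(miss)) stop("columns not in cohort: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(cohort[columns])
  if (!any(keep)) stop("complete-case restriction removed every row")
  out <- cohort[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# z-score outcome and determinant on the analysis sample; invert the
# determinant when requested (associations per SD *lower* exposure)
.std_xy <- function(cohort, outcome, determinant, invert) {
  y <- .zscore(cohort[[outcome]], outcome)
  x <- .zscore(cohort[[determinant]], determinant)
  if (invert) x <- -x
  list(y = y, x = x)
}

#' Standardized-beta regression for one model of the ladder
#'
#' Outcome and determinant are z-scored on the analysis sample; the
#' determinant is multiplied by -1 when `invert = TRUE` so the coefficient
#' reads per SD lower exposure; ordinary least squares with the listed
#' covariates; the standardized beta is the coefficient on the determinant
#' with its t-based 95% CI and p-value.
#'
#' @param cohort Complete-case data frame.
#' @param outcome,determinant Numeric column names.
#' @param covariates Character vector of covariate columns (may be empty).
#' @param invert Invert the determinant (default TRUE).
#' @param prestandardized Skip internal z-scoring (used by the stratified
#'   analysis, which standardizes on the full analysis sample).
#' @return One-row data frame: `st_beta`, `lo`, `hi`, `p`, `n`.
#' @export
standardized_fit <- function(cohort, outcome, determinant, covariates = character(0),
                             invert = TRUE, prestandardized = FALSE) {
  if (prestandardized) {
    y <- cohort[[outcome]]
    x <- if (invert) -cohort[[determinant]] else cohort[[determinant]]
  } else {
    s <- .std_xy(cohort, outcome, determinant, invert)
    y <- s$y; x <- s$x
  }
  dat <- data.frame(.y = y, .x = x)
  for (cv in covariates) dat[[cv]] <- cohort[[cv]]
  fml <- stats::reformulate(c(".x", covariates), response = ".y")
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; aliased terms: ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  est <- sm[".x", "Estimate"]; se <- sm[".x", "Std. Error"]
  tq <- stats::qt(0.975, fit$df.residual)
  data.frame(st_beta = est, lo = est - tq * se, hi = est + tq * se,
             p = sm[".x", "Pr(>|t|)"], n = nrow(dat))
}

#' Run the full association ladder
#'
#' Fits the five-model covariate ladder for every exposure x outcome pair
#' (by default the two HRV composites against the beta-cell composite and
#' the five individual indices: a 2 x 6 x 5 grid, 60 rows), on a single
#' complete-case row set shared across the whole ladder.
#'
#' @param cohort Data frame with exposure, outcome and covariate columns.
#' @param exposures,outcomes Column names (defaults as in the tables).
#' @param models Named list of covariate sets (default [ladder_covariates()]).
#' @param invert Report associations per SD lower exposure (default TRUE).
#' @return Object of class `assoc_ladder`: long-format data frame with
#'   columns `exposure`, `outcome`, `model`, `st_beta`, `lo`, `hi`, `p`,
#'   `n`; attribute `n_removed` gives the complete-case removals.
#' @export
run_ladder <- function(cohort,
                       exposures = c("hrv_time_z", "hrv_freq_z"),
                       outcomes = c("betacell_z", "cpeptidogenic",
                                    "overall_secretion", "glucose_sensitivity",
                                    "potentiation_ratio", "rate_sensitivity"),
                       models = ladder_covariates(), invert = TRUE) {
  all_cols <- unique(c(exposures, outcomes, unlist(models)))
  cohort <- complete_case(cohort, all_cols)
  rows <- list()
  for (ex in exposures) for (oc in outcomes) for (mi in seq_along(models)) {
    r <- standardized_fit(cohort, oc, ex, models[[mi]], invert = invert)
    r <- cbind(data.frame(exposure = ex, outcome = oc, model = names(models)[mi]), r)
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_removed") <- attr(cohort, "n_removed")
  class(out) <- c("assoc_ladder", "data.frame")
  out
}

#' @export
print.assoc_ladder <- function(x, digits = 3, ...) {
  cat("Standardized-beta association ladder (", nrow(x), " fits, n = ",
      x$n[1L], ")\n", sep = "")
  d <- as.data.frame(x)
  d$st_beta <- round(d$st_beta, digits)
  d$ci95 <- sprintf("(%.*f, %.*f)", digits, x$lo, digits, x$hi)
  d$p <- signif(d$p, 2)
  print(d[, c("exposure", "outcome", "model", "st_beta", "ci95", "p", "n")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.assoc_ladder <- function(object, ...) {
  cat("Fully adjusted (m3b) standardized betas:\n")
  print(as.data.frame(object[object$model == "m3b",
                             c("exposure", "outcome", "st_beta", "lo", "hi", "p")]),
        row.names = FALSE)
  invisible(object)
}

#' Effect-modification test
#'
#' Augments the fully adjusted model with interaction terms between the
#' modifier and the determinant AND between the modifier and every
#' covariate, and tests the determinant-interaction term(s) with an F test
#' (a joint 2-df test when the modifier has three levels, e.g. glucose
#' metabolism status).
#'
#' @param cohort Complete-case data frame.
#' @param outcome,determinant Numeric column names.
#' @param modifier Categorical column with >= 2 levels (`sex`, `gms`, ...).
#' @param covariates Covariate set (default fully adjusted model 3B).
#' @param invert Invert the determinant (default TRUE).
#' @return One-row data frame `p_interaction`, `df`, `n`.
#' @export
interaction_test <- function(cohort, outcome, determinant, modifier,
                             covariates = ladder_covariates()$m3b,
                             invert = TRUE) {
  mod <- droplevels(factor(cohort[[modifier]]))
  if (nlevels(mod) < 2L) stop("modifier must have at least 2 levels")
  if (any(table(mod) < 10L)) warning("modifier level with fewer than 10 observations")
  s <- .std_xy(cohort, outcome, determinant, invert)
  dat <- data.frame(.y = s$y, .x = s$x, .mod = mod)
  covariates <- setdiff(covariates, modifier)
  for (cv in covariates) dat[[cv]] <- cohort[[cv]]
  rhs_main <- c(".x", covariates)
  f_full <- stats::as.formula(paste(
    ".y ~ (", paste(rhs_main, collapse = " + "), ") * .mod"))
  f_red <- stats::as.formula(paste(
    ".y ~ ", paste(rhs_main, collapse = " + "), " + .mod + ",
    paste(paste0(covariates, ":.mod"), collapse = " + ")))
  if (!length(covariates))
    f_red <- stats::as.formula(".y ~ .x + .mod")
  full <- stats::lm(f_full, data = dat)
  red <- stats::lm(f_red, data = dat)
  an <- stats::anova(red, full)
  data.frame(p_interaction = an$`Pr(>F)`[2L], df = an$Df[2L], n = nrow(dat))
}

#' Glucose-metabolism-stratified ladder
#'
#' Runs the full ladder within each stratum. Outcome and determinant are
#' z-scored on the full analysis sample (not per stratum) so stratum
#' estimates share a scale.
#'
#' @param cohort Data frame.
#' @param strata Stratifying column (default `"gms"`).
#' @param exposures,outcomes,models,invert As in [run_ladder()].
#' @param min_per_stratum Strata smaller than covariate count + 2 (or this
#'   floor) are skipped with a warning.
#' @return Named list of `assoc_ladder` objects, one per retained stratum.
#' @export
stratified_ladder <- function(cohort, strata = "gms",
                              exposures = c("hrv_time_z", "hrv_freq_z"),
                              outcomes = "betacell_z",
                              models = ladder_covariates(), invert = TRUE,
                              min_per_stratum = NULL) {
  all_cols <- unique(c(exposures, outcomes, unlist(models), strata))
  cohort <- complete_case(cohort, all_cols)
  for (cl in c(exposures, outcomes)) cohort[[cl]] <- .zscore(cohort[[cl]], cl)
  need <- max(length(models[[length(models)]]) + 2L, min_per_stratum)
  res <- list()
  for (lev in levels(droplevels(factor(cohort[[strata]])))) {
    sub <- cohort[cohort[[strata]] == lev, , drop = FALSE]
    if (nrow(sub) < need) {
      warning("stratum ", lev, " too small (", nrow(sub), "); skipped")
      next
    }
    rows <- list()
    for (ex in exposures) for (oc in outcomes) for (mi in seq_along(models)) {
      r <- standardized_fit(sub, oc, ex, models[[mi]], invert = invert,
                            prestandardized = TRUE)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(exposure = ex, outcome = oc, model = names(models)[mi]), r)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    class(tab) <- c("assoc_ladder", "data.frame")
    res[[lev]] <- tab
  }
  res
}

#' Tertile logistic analysis for a skewed outcome
#'
#' Categorizes the outcome into tertiles at the 33.3/66.7 sample
#' percentiles and fits a logistic regression of the top tertile versus the
#' lower two (default contrast) on the z-scored, inverted determinant plus
#' the ladder covariates; reports the odds ratio per SD lower exposure.
#'
#' @param cohort Complete-case data frame.
#' @param outcome Skewed numeric outcome (default `"rate_sensitivity"`).
#' @param determinant Exposure column.
#' @param covariates Covariate set (default model 3B).
#' @param contrast `"top"` (top tertile vs rest) or `"bottom"`.
#' @param invert Invert the determinant (default TRUE).
#' @return One-row data frame: `or`, `lo`, `hi`, `p`, `cut1`, `cut2`, `n`.
#' @export
tertile_logistic <- function(cohort, outcome = "rate_sensitivity", determinant,
                             covariates = ladder_covariates()$m3b,
                             contrast = c("top", "bottom"), invert = TRUE) {
  contrast <- match.arg(contrast)
  y <- cohort[[outcome]]
  if (length(unique(y)) < 3L) stop("need at least 3 distinct outcome values")
  cuts <- stats::quantile(y, c(1, 2) / 3, names = FALSE)
  if (cuts[1L] == cuts[2L])
    stop(sprintf("ties collapse a tertile (cut points %.4g, %.4g)", cuts[1L], cuts[2L]))
  bin <- if (contrast == "top") as.integer(y > cuts[2L]) else as.integer(y <= cuts[1L])
  x <- .zscore(cohort[[determinant]], determinant)
  if (invert) x <- -x
  dat <- data.frame(.y = bin, .x = x)
  for (cv in covariates) dat[[cv]] <- cohort[[cv]]
  fml <- stats::reformulate(c(".x", covariates), response = ".y")
  fit <- stats::glm(fml, data = dat, family = stats::binomial())
  sm <- summary(fit)$coefficients
  est <- sm[".x", "Estimate"]; se <- sm[".x", "Std. Error"]
  data.frame(or = exp(est), lo = exp(est - 1.96 * se), hi = exp(est + 1.96 * se),
             p = sm[".x", "Pr(>|z|)"], cut1 = cuts[1L], cut2 = cuts[2L], n = nrow(dat))
}
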