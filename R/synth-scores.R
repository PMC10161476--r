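# Score-level synthetic cohort generation.

# --- truncated-normal machinery (moment-matched) -------------------------

.tn_cache <- new.env(parent = emptyenv())

# analytic mean/sd of Normal(mu, sigma) truncated to [lo, hi]
.tn_moments <- function(mu, sigma, lo, hi) {
  al <- (lo - mu) / sigma; be <- (hi - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# solve (mu0, sigma0) so the truncated distribution has the target moments
.tn_params <- function(mean, sd, lo, hi) {
  key <- paste(mean, sd, lo, hi, sep = "_")
  if (!is.null(.tn_cache[[key]])) return(.tn_cache[[key]])
  obj <- function(p) {
    m <- .tn_moments(p[1L], exp(p[2L]), lo, hi)
    (m[1L] - mean)^2 + (m[2L] - sd)^2
  }
  op <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 5000))
  res <- list(mu = op$par[1L], sigma = exp(op$par[2L]), lo = lo, hi = hi,
              target = c(mean, sd))
  .tn_cache[[key]] <- res
  res
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- .tn_params(mean, sd, lo, hi)
  u <- stats::runif(n, stats::pnorm((lo - p$mu) / p$sigma),
                    stats::pnorm((hi - p$mu) / p$sigma))
  p$mu + p$sigma * stats::qnorm(u)
}

# lognormal parameterized by median and sdlog, with analytic moments
.lognorm_moments <- function(median, sdlog) {
  mu <- log(median)
  m <- exp(mu + sdlog^2 / 2)
  s <- sqrt((exp(sdlog^2) - 1)) * m
  c(mean = m, sd = s)
}

# marginals calibrated to the cohort description (age 60 +/- 8 within
# 40-75; 52% men; gms 60/16/24%; remaining continuous covariates matched to
# the printed means/SDs or median/IQR)
.cov_marginals <- list(
  age = list(mean = 60, sd = 8, lo = 40, hi = 75),
  matsuda = list(median = 3.46, sdlog = 0.601),
  bmi = list(mean = 26.72, sd = 4.23),
  office_sbp = list(mean = 134.59, sd = 17.94),
  chol_hdl_ratio = list(median = 3.53, sdlog = 0.310),
  waist = list(mean = 95.05, sd = 12.81),
  egfr = list(mean = 88.32, sd = 14.31),
  energy_intake = list(mean = 9215, sd = 2553),
  physical_activity = list(mean = 14.31, sd = 8.08))

.cat_levels <- list(
  sex = c(M = 0.52, F = 0.48),
  education = c(low = 0.32, middle = 0.27, high = 0.41),
  gms = c(NGM = 0.60, prediabetes = 0.16, T2D = 0.24),
  smoking = c(never = 0.34, former = 0.53, current = 0.13),
  alcohol = c(none = 0.17, moderate = 0.56, high = 0.27))

.draw_cat <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

# population-moment standardization of a generated continuous covariate
.std_cov <- function(name, x) {
  m <- .cov_marginals[[name]]
  if (!is.null(m$median)) {
    mm <- .lognorm_moments(m$median, m$sdlog)
    (x - mm["mean"]) / mm["sd"]
  } else {
    (x - m$mean) / m$sd
  }
}

#' Draw cohort covariates with the study's marginal structure
#'
#' Generates the covariate table of a synthetic cohort: age from a
#' moment-matched truncated normal on [40, 75] (realized mean 60, SD 8),
#' sex Bernoulli(0.52), glucose metabolism status multinomial
#' (0.60/0.16/0.24 for NGM/prediabetes/T2D), and the remaining covariates
#' with marginals matched to the printed cohort description. With
#' `gms_correlated = TRUE` (signal-level default) the metabolic covariates
#' (Matsuda, BMI, fasting glucose, medication probabilities) shift with
#' glucose metabolism status; with `FALSE` (score-level default) all
#' covariates are mutually independent so the SEM calibration is exact.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param gms_correlated Couple metabolic covariates to gms (default FALSE).
#' @param include_excluded Also generate insulin users / fasting glucose
#'   above 11 mmol/L for exercising the exclusion cascade (default FALSE).
#' @return Data frame, one row per subject, with `id` and covariates.
#' @details Each covariate column is drawn from its own seeded substream of
#'   the master seed, so subject k's values are reproducible independent of
#'   the cohort size.
#' @export
draw_covariates <- function(n, seed = 1L, gms_correlated = FALSE,
                            include_excluded = FALSE) {
  if (n < 1L) stop("n must be >= 1")
  stream <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      set.seed(as.integer((as.numeric(seed) * 2654435 + i * 97561) %% 2147483629))
    }
  })
  a <- .cov_marginals
  d <- data.frame(id = sprintf("S%05d", seq_len(n)))
  stream(); d$age <- .rtruncnorm(n, a$age$mean, a$age$sd, a$age$lo, a$age$hi)
  for (nm in names(.cat_levels)) {
    stream(); d[[nm]] <- .draw_cat(n, .cat_levels[[nm]])
  }
  gshift <- function(base, by_gms) base + by_gms[as.integer(d$gms)]
  if (gms_correlated) {
    stream(); d$matsuda <- exp(log(a$matsuda$median) + gshift(0, c(0.15, -0.10, -0.45)) +
                                 stats::rnorm(n, 0, a$matsuda$sdlog))
    stream(); d$bmi <- stats::rnorm(n, gshift(a$bmi$mean, c(-0.8, 0.7, 1.6)), a$bmi$sd * 0.9)
    stream(); d$fasting_glucose <- .rtruncnorm(n, 5.2, 0.4, 3.5, 7.0) *
      c(1, 1.13, 1.50)[as.integer(d$gms)]
    stream(); d$lipid_med <- stats::rbinom(n, 1, c(0.25, 0.35, 0.55)[as.integer(d$gms)])
    stream(); d$antihyp_med <- stats::rbinom(n, 1, c(0.30, 0.40, 0.55)[as.integer(d$gms)])
  } else {
    stream(); d$matsuda <- exp(log(a$matsuda$median) + stats::rnorm(n, 0, a$matsuda$sdlog))
    stream(); d$bmi <- stats::rnorm(n, a$bmi$mean, a$bmi$sd)
    stream(); d$fasting_glucose <- .rtruncnorm(n, 5.2, 0.4, 3.5, 7.0) *
      c(1, 1.13, 1.50)[as.integer(d$gms)]
    stream(); d$lipid_med <- stats::rbinom(n, 1, 0.33)
    stream(); d$antihyp_med <- stats::rbinom(n, 1, 0.37)
  }
  stream(); d$office_sbp <- stats::rnorm(n, a$office_sbp$mean, a$office_sbp$sd)
  stream(); d$chol_hdl_ratio <- exp(log(a$chol_hdl_ratio$median) +
                                      stats::rnorm(n, 0, a$chol_hdl_ratio$sdlog))
  stream(); d$waist <- stats::rnorm(n, a$waist$mean, a$waist$sd)
  stream(); d$egfr <- stats::rnorm(n, a$egfr$mean, a$egfr$sd)
  stream(); d$energy_intake <- pmax(1000, stats::rnorm(n, a$energy_intake$mean,
                                                       a$energy_intake$sd))
  stream(); d$physical_activity <- pmax(0, stats::rnorm(n, a$physical_activity$mean,
                                                        a$physical_activity$sd))
  stream(); d$cvd_history <- stats::rbinom(n, 1, 0.16)
  stream()
  d$insulin_use <- if (include_excluded) {
    as.integer(d$gms == "T2D" & stats::runif(n) < 0.10)
  } else 0L
  stream()
  if (include_excluded) {
    hi <- d$gms == "T2D" & stats::runif(n) < 0.08
    d$fasting_glucose[hi] <- stats::runif(sum(hi), 11.1, 15)
  }
  d
}

#' Draw a calibrated score-level synthetic cohort
#'
#' Generates a cohort table from a [sem_config()]: mutually independent
#' standardized confounders realized as covariate columns with realistic
#' marginals, an exposure composite (the HRV domain named in the config,
#' on the natural scale: higher = more HRV), and the six beta-cell outcome
#' scores, each with its calibrated crude/adjusted population coefficients.
#' The non-calibrated HRV domain is added as an auxiliary composite
#' correlated 0.9 with the calibrated one. Reproducible: the output is a
#' pure function of (config, seed).
#'
#' @param config A [sem_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Data frame with `id`, covariates, `hrv_time_z`, `hrv_freq_z` and
#'   outcome columns `betacell_z`, `cpeptidogenic`, `overall_secretion`,
#'   `glucose_sensitivity`, `potentiation_ratio`, `rate_sensitivity` (all
#'   outcome scores standardized).
#' @export
draw_cohort_scores <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sem_config"))
  n <- config$n_subjects
  if (is.null(seed)) seed <- config$seed
  cov <- draw_covariates(n, seed = seed, gms_correlated = FALSE)
  # standardized confounder matrix in the config's declared order
  C <- sapply(config$confounders$name, function(nm) .std_cov(nm, cov[[nm]]))
  a <- config$confounders$a
  sp1 <- config$paths[[1L]]
  substream <- function(k) set.seed(.subject_seed(seed, 500000L + k))
  substream(0L)
  x <- as.numeric(C %*% a) + stats::rnorm(n, 0, sp1$sd_ex)
  out <- cov
  for (k in seq_along(config$paths)) {
    sp <- config$paths[[k]]
    substream(k)
    out[[names(config$paths)[k]]] <-
      sp$d * x + as.numeric(C %*% sp$conf$b) + stats::rnorm(n, 0, sp$sd_ey)
  }
  substream(99L)
  aux <- 0.9 * x + sqrt(1 - 0.9^2) * stats::rnorm(n)
  if (config$domain == "time") {
    out$hrv_time_z <- x
    out$hrv_freq_z <- aux
  } else {
    out$hrv_freq_z <- x
    out$hrv_time_z <- aux
  }
  attr(out, "sem_config") <- config
  out
}
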