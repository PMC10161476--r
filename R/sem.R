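# Structural-equation calibration for the score-level synthetic cohort.
#
# Standardized linear Gaussian SEM:
#   X  = sum_i a_i C_i + e_x,             var(X) = 1
#   Y_k = d_k X + sum_i b_ki C_i + e_k,   var(Y_k) = 1
# with mutually independent standardized confounders C_i. Closed form:
# population crude coefficient of Y_k on X is d_k + sum_i a_i b_ki; the
# confounder-adjusted coefficient is d_k. Residual SDs are solved (not
# free) so every node has unit variance.

#' Solve SEM paths for requested crude and adjusted coefficients
#'
#' Given a crude and an adjusted (confounder-controlled) standardized
#' regression target and exposure-side confounder paths `a_i`, solves the
#' outcome-side paths `b_i = kappa * w_i` so that the population crude
#' coefficient equals `crude_target` while the adjusted coefficient equals
#' `adjusted_target` (`d = adjusted_target`,
#' `sum(a_i * b_i) = crude_target - adjusted_target`).
#'
#' @param crude_target,adjusted_target Standardized coefficients, |.| < 1.
#' @param confounder_spec Data frame with columns `name`, `a` (path from
#'   confounder to exposure) and optionally `w` (relative outcome-path
#'   weights, default `a`).
#' @return List of class `sem_paths`: `d`, data frame `conf` (`name`, `a`,
#'   `b`), residual SDs `sd_ex`, `sd_ey`, and the implied `crude`.
#' @examples
#' sp <- solve_sem_paths(-0.070, -0.055,
#'                       data.frame(name = "c1", a = 0.3, w = 1))
#' sp$d + sum(sp$conf$a * sp$conf$b)  # -0.070
#' @export
solve_sem_paths <- function(crude_target, adjusted_target, confounder_spec) {
  if (abs(crude_target) >= 1 || abs(adjusted_target) >= 1)
    stop("standardized targets must have magnitude < 1")
  cs <- as.data.frame(confounder_spec)
  if (!all(c("name", "a") %in% names(cs))) stop("confounder_spec needs columns name, a")
  if (is.null(cs$w)) cs$w <- cs$a
  gap <- crude_target - adjusted_target
  denom <- sum(cs$a * cs$w)
  if (gap != 0 && denom == 0)
    stop("infeasible: confounder paths cannot produce a crude-adjusted gap")
  kappa <- if (denom == 0) 0 else gap / denom
  cs$b <- kappa * cs$w
  d <- adjusted_target
  var_ex <- 1 - sum(cs$a^2)
  var_ey <- 1 - (d^2 + sum(cs$b^2) + 2 * d * sum(cs$a * cs$b))
  if (var_ex <= 0 || var_ey <= 0)
    stop("infeasible: requested paths imply non-positive residual variance")
  structure(list(d = d, conf = cs, sd_ex = sqrt(var_ex), sd_ey = sqrt(var_ey),
                 crude = d + sum(cs$a * cs$b)),
            class = "sem_paths")
}

# Table of default per-outcome calibration targets on the natural HRV scale
# (positive: higher HRV, higher beta-cell response; ladder inversion reports
# them per SD *lower* HRV with a negative sign). Crude and fully adjusted
# (model 3B) standardized coefficients for each outcome, per exposure domain.
.sem_default_targets <- function(domain = c("time", "freq")) {
  domain <- match.arg(domain)
  if (domain == "time") {
    data.frame(
      outcome = c("betacell_z", "cpeptidogenic", "overall_secretion",
                  "glucose_sensitivity", "potentiation_ratio", "rate_sensitivity"),
      crude = c(0.070, 0.061, 0.010, 0.040, 0.073, 0.038),
      adjusted = c(0.055, 0.049, 0.037, 0.037, 0.038, 0.012))
  } else {
    data.frame(
      outcome = c("betacell_z", "cpeptidogenic", "overall_secretion",
                  "glucose_sensitivity", "potentiation_ratio", "rate_sensitivity"),
      crude = c(0.073, 0.061, 0.014, 0.044, 0.073, 0.038),
      adjusted = c(0.051, 0.048, 0.035, 0.036, 0.035, 0.008))
  }
}

# standardized-confounder definitions shared by the score-level generator:
# exposure-side paths on the natural HRV scale (older age, higher BMI and
# higher blood pressure -> lower HRV; better insulin sensitivity -> higher)
.sem_default_confounders <- function() {
  data.frame(name = c("age", "matsuda", "bmi", "office_sbp"),
             a = c(-0.30, 0.15, -0.20, -0.15))
}

#' Build a calibrated score-level SEM cohort configuration
#'
#' Assembles the full configuration for [draw_cohort_scores()]: one exposure
#' domain whose per-outcome crude and fully-adjusted population coefficients
#' are calibrated simultaneously for all six beta-cell outcomes (composite
#' plus five indices), sharing the exposure-side confounder paths.
#'
#' @param n_subjects Cohort size (default 2007).
#' @param domain Exposure domain to calibrate: `"time"` or `"freq"`.
#' @param targets Optional data frame `outcome`, `crude`, `adjusted`
#'   overriding the default calibration (natural HRV scale, positive).
#' @param confounders Optional data frame `name`, `a` of exposure-side
#'   paths; names must be standardized continuous covariates known to the
#'   generator (age, matsuda, bmi, office_sbp).
#' @param seed Integer master seed.
#' @return List of class `sem_config`.
#' @export
sem_config <- function(n_subjects = 2007, domain = c("time", "freq"),
                       targets = NULL, confounders = NULL, seed = 1L) {
  domain <- match.arg(domain)
  if (is.null(targets)) targets <- .sem_default_targets(domain)
  if (is.null(confounders)) confounders <- .sem_default_confounders()
  if (n_subjects < nrow(confounders) + 3L)
    stop("n_subjects too small for the model terms")
  paths <- lapply(seq_len(nrow(targets)), function(k)
    solve_sem_paths(targets$crude[k], targets$adjusted[k], confounders))
  names(paths) <- targets$outcome
  structure(list(n_subjects = as.integer(n_subjects), domain = domain,
                 targets = targets, confounders = confounders,
                 paths = paths, seed = as.integer(seed)),
            class = "sem_config")
}

#' @export
print.sem_config <- function(x, ...) {
  cat(sprintf("Score-level SEM cohort config: n=%d, exposure domain=%s, seed=%d\n",
              x$n_subjects, x$domain, x$seed))
  cat("Calibrated population coefficients (natural HRV scale):\n")
  print(x$targets, row.names = FALSE)
  invisible(x)
}
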