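#' Construct and validate a 7-point OGTT record
#'
#' @param t_min Sample times; must be exactly 0, 15, 30, 45, 60, 90, 120.
#' @param glucose_mmol_l,cpeptide_pmol_l,insulin_pmol_l Concentrations at
#'   each sample time; all must be positive.
#' @return Data frame of class `ogtt_record` with attribute
#'   `fasting_glucose_mmol_l` (the value at t = 0).
#' @export
ogtt_record <- function(t_min, glucose_mmol_l, cpeptide_pmol_l, insulin_pmol_l) {
  o <- order(t_min)
  t_min <- t_min[o]
  if (!identical(as.numeric(t_min), .ogtt_times))
    stop("OGTT requires exactly the sample times 0, 15, 30, 45, 60, 90, 120 min")
  d <- data.frame(t_min = t_min,
                  glucose_mmol_l = glucose_mmol_l[o],
                  cpeptide_pmol_l = cpeptide_pmol_l[o],
                  insulin_pmol_l = insulin_pmol_l[o])
  if (any(unlist(d[-1L]) <= 0)) stop("all concentrations must be positive")
  attr(d, "fasting_glucose_mmol_l") <- d$glucose_mmol_l[1L]
  class(d) <- c("ogtt_record", "data.frame")
  d
}

#' OGTT eligibility rule
#'
#' A subject is ineligible for the OGTT (and hence for beta-cell response
#' estimation) when they use insulin or their fasting plasma glucose is
#' strictly above 11.0 mmol/L.
#'
#' @param insulin_use Logical flag (or 0/1).
#' @param fasting_glucose_mmol_l Fasting plasma glucose, mmol/L.
#' @return Logical: `TRUE` when eligible.
#' @examples
#' ogtt_eligibility(FALSE, 11.0)  # TRUE: exactly 11.0 passes
#' ogtt_eligibility(FALSE, 11.1)  # FALSE
#' @export
ogtt_eligibility <- function(insulin_use, fasting_glucose_mmol_l) {
  !(as.logical(insulin_use) | fasting_glucose_mmol_l > 11.0)
}

#' C-peptidogenic index
#'
#' Early-secretion index: the rise in C-peptide from baseline to 30 minutes
#' divided by the corresponding rise in glucose,
#' `(CP30 - CP0) / (G30 - G0)`. When the glucose denominator is zero the
#' index is undefined and `NA` is returned; a negative denominator is
#' retained but flagged with a warning.
#'
#' @param ogtt An [ogtt_record()] (any data frame with the 7-point columns).
#' @return Numeric scalar (no unit as printed in cohort tables).
#' @export
cpeptidogenic_index <- function(ogtt) {
  g <- ogtt$glucose_mmol_l[match(c(0, 30), ogtt$t_min)]
  cp <- ogtt$cpeptide_pmol_l[match(c(0, 30), ogtt$t_min)]
  if (anyNA(g) || anyNA(cp)) stop("t = 0 and t = 30 samples required")
  dg <- g[2L] - g[1L]
  if (dg == 0) {
    warning("zero glucose increment at 30 min: C-peptidogenic index undefined")
    return(NA_real_)
  }
  if (dg < 0) warning("negative glucose increment at 30 min: index retained but flagged")
  (cp[2L] - cp[1L]) / dg
}

#' Trapezoidal area under the curve
#'
#' @param t Time points (minutes), strictly increasing, at least two.
#' @param y Values at `t`; `NA` pairs are dropped (trapezoid over the
#'   available points, with a message).
#' @return The trapezoidal area over the observed range.
#' @examples
#' auc_trapezoid(c(0, 120), c(0, 120))  # 7200
#' @export
auc_trapezoid <- function(t, y) {
  keep <- !is.na(y)
  if (!all(keep)) {
    message("auc_trapezoid: dropping ", sum(!keep), " missing point(s)")
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 2L) stop("need at least two points")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  sum(diff(t) * (y[-1L] + y[-length(y)]) / 2)
}

#' Overall insulin secretion: CP AUC over glucose AUC
#'
#' @param ogtt An [ogtt_record()].
#' @return The ratio of the trapezoidal AUC of C-peptide to that of glucose
#'   over 0-120 min (no unit).
#' @export
overall_insulin_secretion <- function(ogtt) {
  auc_trapezoid(ogtt$t_min, ogtt$cpeptide_pmol_l) /
    auc_trapezoid(ogtt$t_min, ogtt$glucose_mmol_l)
}

#' Matsuda index of whole-body insulin sensitivity
#'
#' `10000 / sqrt(G0 * I0 * Gmean * Imean)` with glucose in mg/dL and insulin
#' in uU/mL; means are taken over all seven OGTT samples. Inputs in mmol/L
#' and pmol/L are converted with 1 mmol/L = 18.016 mg/dL and
#' 1 uU/mL = 6.0 pmol/L.
#'
#' @param ogtt An [ogtt_record()] (glucose in mmol/L, insulin in pmol/L).
#' @return Numeric scalar; `NA` when any term is non-positive.
#' @export
matsuda_index <- function(ogtt) {
  g_mgdl <- ogtt$glucose_mmol_l * 18.016
  i_uuml <- ogtt$insulin_pmol_l / 6.0
  terms <- c(g_mgdl[ogtt$t_min == 0], i_uuml[ogtt$t_min == 0],
             mean(g_mgdl), mean(i_uuml))
  if (any(!is.finite(terms)) || any(terms <= 0)) return(NA_real_)
  10000 / sqrt(prod(terms))
}

#' Per-subject beta-cell response profile
#'
#' Combines the two formula-based indices with the three model-based
#' parameters into the five-component profile used for the composite score.
#'
#' @param ogtt An [ogtt_record()].
#' @param kinetics A [cpeptide_kinetics()] object.
#' @param fit Optional pre-computed [fit_betacell()] result.
#' @param ... Passed to [fit_betacell()].
#' @return One-row data frame with `cpeptidogenic`, `overall_secretion`,
#'   `glucose_sensitivity`, `potentiation_ratio`, `rate_sensitivity` and
#'   `matsuda`.
#' @export
betacell_profile <- function(ogtt, kinetics, fit = NULL, ...) {
  if (is.null(fit)) fit <- fit_betacell(ogtt, kinetics, ...)
  cf <- coef(fit)
  data.frame(
    cpeptidogenic = suppressWarnings(cpeptidogenic_index(ogtt)),
    overall_secretion = overall_insulin_secretion(ogtt),
    glucose_sensitivity = if (fit$converged) cf[["glucose_sensitivity"]] else NA_real_,
    potentiation_ratio = if (fit$converged) cf[["potentiation_ratio"]] else NA_real_,
    rate_sensitivity = if (fit$converged) cf[["rate_sensitivity"]] else NA_real_,
    matsuda = matsuda_index(ogtt))
}

.betacell_cols <- c("cpeptidogenic", "overall_secretion", "glucose_sensitivity",
                    "potentiation_ratio", "rate_sensitivity")

#' Overall beta-cell response composite z-score
#'
#' Each of the five beta-cell indices is z-scored against the analysis
#' sample; the composite is the mean of the five z-scores, re-standardized
#' to mean 0 and SD 1 on the analysis sample. Computed only for subjects
#' with all five components present (complete case): rows with any missing
#' component receive `NA`.
#'
#' @param profiles Data frame with the five index columns (see
#'   [betacell_profile()]).
#' @return `profiles` with an added `betacell_z` column.
#' @export
betacell_composite <- function(profiles) {
  profiles <- as.data.frame(profiles)
  miss <- setdiff(.betacell_cols, names(profiles))
  if (length(miss)) stop("missing beta-cell index columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(profiles[.betacell_cols])
  if (sum(cc) < 2L) stop("need at least two complete subjects")
  z <- sapply(.betacell_cols, function(cl) .zscore(profiles[[cl]][cc], cl))
  comp <- rowMeans(z)
  out <- rep(NA_real_, nrow(profiles))
  out[cc] <- .zscore(comp, "beta-cell composite")
  profiles$betacell_z <- out
  profiles
}
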