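# Signal-level synthesis: raw beat series and OGTT curves that exercise the
# HRV and beta-cell metric code end-to-end.

# per-subject substream: subject k is reproducible independent of cohort size
.subject_seed <- function(master, k) {
  as.integer((as.numeric(master) * 1000003 + as.numeric(k) * 10007) %% 2147483629)
}

#' Synthesize a labelled 24-hour beat series
#'
#' Builds an RR-interval process containing circadian (24-h period), VLF
#' (0.01 Hz), LF-band (0.1 Hz) and HF-band (0.25 Hz) sinusoidal modulation
#' plus white beat-to-beat noise, all amplitudes scaled by the subject's
#' latent autonomic score (`scale = max(0.05, 1 + latent_gain * latent_autonomic)`), and emits beat times with a configurable fraction of
#' beats labelled ectopic or artifact. Beat times are obtained by a
#' vectorized fixed-point pass of `t[k+1] = t[k] + RR(t[k])`.
#'
#' @param latent_autonomic Latent autonomic z-score (higher = more HRV).
#' @param duration_h Recording duration, hours (> 0).
#' @param mean_rr_ms Mean RR interval, ms, in [300, 2000].
#' @param modulation Named list of amplitudes in ms: `circadian`, `vlf`,
#'   `lf`, `hf`, `white` (beat-to-beat noise SD) and `latent_gain`.
#' @param ectopic_fraction,artifact_fraction Fractions of beats labelled
#'   `"E"` / `"A"`.
#' @param seed Integer seed.
#' @return A [beat_series()].
#' @export
synthesize_beat_series <- function(latent_autonomic = 0, duration_h = 24,
                                   mean_rr_ms = 800,
                                   modulation = list(circadian = 140, vlf = 46,
                                                     lf = 26, hf = 13, white = 25,
                                                     latent_gain = 0.12),
                                   ectopic_fraction = 0.03,
                                   artifact_fraction = 0.01, seed = 1L) {
  if (duration_h <= 0) stop("duration_h must be > 0")
  if (mean_rr_ms < 300 || mean_rr_ms > 2000) stop("mean_rr_ms must be in [300, 2000]")
  set.seed(seed)
  m <- utils::modifyList(list(circadian = 140, vlf = 46, lf = 26, hf = 13,
                              white = 25, latent_gain = 0.12), as.list(modulation))
  sc <- max(0.05, 1 + m$latent_gain * latent_autonomic)
  dur_s <- duration_h * 3600
  ph <- stats::runif(4, 0, 2 * pi)
  comp <- cbind(amp = c(m$circadian, m$vlf, m$lf, m$hf),
                freq = c(1 / 86400, 0.01, 0.1, 0.25), phase = ph)
  comp <- comp[comp[, "amp"] != 0, , drop = FALSE]
  rr_det <- function(t) {
    out <- rep(mean_rr_ms, length(t))
    for (j in seq_len(nrow(comp)))
      out <- out + sc * comp[j, "amp"] *
        sin(2 * pi * comp[j, "freq"] * t + comp[j, "phase"])
    out
  }
  n <- ceiling(dur_s / (mean_rr_ms / 1000) * 1.25) + 10L
  tt <- cumsum(rep(mean_rr_ms / 1000, n))
  for (it in 1:2) {                       # fixed point on t[k+1] = t[k] + RR(t[k])
    rr <- rr_det(c(0, tt[-n]))
    tt <- cumsum(rr / 1000)
  }
  rr <- rr_det(c(0, tt[-n]))
  if (m$white > 0) rr <- rr + stats::rnorm(n, 0, sc * m$white)
  rr <- pmax(rr, 0.35 * mean_rr_ms)
  tt <- cumsum(rr / 1000)
  keep <- tt <= dur_s
  tt <- tt[keep]
  n <- length(tt)
  lab <- rep("N", n)
  n_bad <- round((ectopic_fraction + artifact_fraction) * n)
  if (n_bad > 0) {
    bad <- sample(n, n_bad)
    n_e <- round(ectopic_fraction * n)
    lab[bad[seq_len(min(n_e, n_bad))]] <- "E"
    if (n_bad > n_e) lab[bad[(n_e + 1L):n_bad]] <- "A"
  }
  beat_series(tt, lab, duration_h = duration_h)
}

# piecewise-linear glucose excursion templates at the 7 OGTT times (mmol/L);
# editable defaults, one per glucose metabolism class
.glucose_templates <- list(
  NGM = c(5.2, 7.0, 8.2, 8.0, 7.2, 6.0, 5.4),
  prediabetes = c(5.9, 7.8, 9.6, 10.2, 10.0, 8.8, 7.8),
  T2D = c(7.5, 9.3, 11.5, 12.8, 13.5, 13.2, 12.0))

# insulin generation: basal level and incremental insulin-per-C-peptide
# factor per class; prediabetes produces the highest insulin excursions
.insulin_pars <- list(
  NGM = c(basal = 48, phi = 0.10),
  prediabetes = c(basal = 95, phi = 0.24),
  T2D = c(basal = 80, phi = 0.13))

#' Synthesize a 7-point OGTT record from beta-cell truth parameters
#'
#' C-peptide is produced by forward-simulating the secretion model through
#' two-compartment kinetics on the class-specific piecewise-linear glucose
#' template, then multiplied by lognormal measurement noise with the stated
#' CV. Glucose is the forcing input of the secretion model and is emitted
#' noise-free (the template itself); measurement noise applies to the
#' secretory products (C-peptide, insulin). Insulin is generated from basal
#' class levels plus an incremental component proportional to the C-peptide
#' excursion, with the prediabetes class carrying the largest insulin
#' response. Negative or zero concentrations after noise are floored at a
#' small positive value (with a message).
#'
#' @param truth List with `glucose_sensitivity`, `rate_sensitivity`,
#'   `basal_secretion`, `potentiation_ratio` (linear-in-time potentiation
#'   with time-average 1 and the stated P120/P0 ratio).
#' @param gms `"NGM"`, `"prediabetes"` or `"T2D"` (selects templates).
#' @param kinetics A [cpeptide_kinetics()] object.
#' @param noise_cv Multiplicative measurement noise CV (0 = noise-free).
#' @param seed Integer seed.
#' @param glucose_template Optional 7-value template override (mmol/L).
#' @return An [ogtt_record()] with attribute `truth`.
#' @export
synthesize_ogtt <- function(truth, gms = "NGM", kinetics, noise_cv = 0.04,
                            seed = 1L, glucose_template = NULL) {
  set.seed(seed)
  if (is.null(glucose_template)) glucose_template <- .glucose_templates[[gms]]
  stopifnot(length(glucose_template) == 7L)
  pot <- .linear_potentiation(truth$potentiation_ratio)
  params <- list(glucose_sensitivity = truth$glucose_sensitivity,
                 rate_sensitivity = truth$rate_sensitivity,
                 basal_secretion = truth$basal_secretion,
                 potentiation = pot)
  g <- data.frame(t_min = .ogtt_times, glucose_mmol_l = glucose_template)
  sim <- forward_simulate_ogtt(params, g, kinetics)
  ip <- .insulin_pars[[gms]]
  insulin <- ip[["basal"]] +
    ip[["phi"]] * (sim$cpeptide_pmol_l - sim$cpeptide_pmol_l[1L])
  noisy <- function(x) {
    if (noise_cv <= 0) return(x)
    sdlog <- sqrt(log(1 + noise_cv^2))
    x * exp(stats::rnorm(length(x), -sdlog^2 / 2, sdlog))
  }
  gl <- glucose_template; cp <- noisy(sim$cpeptide_pmol_l); ins <- noisy(insulin)
  if (any(c(gl, cp, ins) <= 0)) {
    message("synthesize_ogtt: flooring non-positive noisy concentrations")
    gl <- pmax(gl, 0.1); cp <- pmax(cp, 1); ins <- pmax(ins, 0.5)
  }
  rec <- ogtt_record(.ogtt_times, gl, cp, ins)
  attr(rec, "truth") <- truth
  rec
}

# time-linear potentiation with time-average 1 over [0, 120] and
# P(120)/P(0) equal to the requested ratio
.linear_potentiation <- function(ratio) {
  if (is.null(ratio) || ratio <= 0) stop("potentiation ratio must be positive")
  beta <- (ratio - 1) / (60 * (1 + ratio))
  alpha <- 1 - 60 * beta
  list(t = c(0, 120), p = c(alpha, alpha + 120 * beta))
}

# map a latent beta-cell score to truth parameters (linear scalings around
# the cohort-typical values; floors keep parameters physiologic)
.betacell_truth <- function(latent) {
  list(glucose_sensitivity = 83 * max(0.1, 1 + 0.25 * latent),
       rate_sensitivity = 724 * max(0.05, 1 + 0.35 * latent),
       basal_secretion = 100 * max(0.2, 1 + 0.15 * latent),
       potentiation_ratio = 1.63 * max(0.15, 1 + 0.25 * latent))
}

#' Simulate a synthetic cohort (score- or signal-level)
#'
#' Score mode draws the calibrated SEM cohort table directly (fast; used
#' for association studies). Signal mode additionally synthesizes, for each
#' subject, a labelled beat series driven by the subject's exposure
#' composite and an OGTT record forward-simulated from beta-cell truth
#' parameters driven by the subject's outcome composite; per-subject seeds
#' are substreams of the master seed.
#'
#' @param n Number of subjects.
#' @param seed Master seed.
#' @param mode `"scores"` or `"signals"`.
#' @param config Optional [sem_config()] (defaults to the time-domain
#'   calibration with `n` subjects).
#' @param duration_h,noise_cv Signal-mode recording duration and OGTT
#'   measurement noise CV.
#' @param out_dir Optional directory: writes `covariates.csv`, `scores.csv`
#'   and per-subject `beats/<ID>.txt`, `ogtt/<ID>.csv`.
#' @return Score mode: the cohort data frame. Signal mode: list with
#'   `scores` (cohort table), `beats` (list of [beat_series()]), `ogtt`
#'   (list of [ogtt_record()]), `truth` (per-subject parameter list).
#' @export
simulate_cohort <- function(n = 2007, seed = 1L, mode = c("scores", "signals"),
                            config = NULL, duration_h = 24, noise_cv = 0.04,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- sem_config(n_subjects = n, seed = seed)
  scores <- draw_cohort_scores(config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(scores[, 1:which(names(scores) == "insulin_use")],
                     file.path(out_dir, "covariates.csv"), row.names = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
  }
  if (mode == "scores") return(scores)

  beats <- vector("list", n); ogtts <- vector("list", n); truths <- vector("list", n)
  names(beats) <- names(ogtts) <- names(truths) <- scores$id
  xcol <- if (config$domain == "time") "hrv_time_z" else "hrv_freq_z"
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "beats"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "ogtt"), showWarnings = FALSE)
  }
  for (k in seq_len(n)) {
    sk <- .subject_seed(seed, k)
    beats[[k]] <- synthesize_beat_series(scores[[xcol]][k], duration_h = duration_h,
                                         seed = sk)
    truths[[k]] <- .betacell_truth(scores$betacell_z[k])
    kin <- cpeptide_kinetics(scores$age[k], as.character(scores$sex[k]),
                             bmi = scores$bmi[k], gms = as.character(scores$gms[k]))
    ogtts[[k]] <- synthesize_ogtt(truths[[k]], gms = as.character(scores$gms[k]),
                                  kinetics = kin, noise_cv = noise_cv, seed = sk + 1L)
    if (!is.null(out_dir)) {
      write_beats(beats[[k]], file.path(out_dir, "beats", paste0(scores$id[k], ".txt")))
      utils::write.csv(as.data.frame(ogtts[[k]]),
                       file.path(out_dir, "ogtt", paste0(scores$id[k], ".csv")),
                       row.names = FALSE)
    }
  }
  list(scores = scores, beats = beats, ogtt = ogtts, truth = truths)
}
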