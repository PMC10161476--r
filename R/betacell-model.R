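# Beta-cell secretion model through two-compartment C-peptide kinetics.
#
# ISR(t) = P(t) * [b0 + s*(G(t) - Gb)] + r * max(dG/dt, 0), floored at 0,
# with s the dose-response slope ("glucose sensitivity", pmol/min/m^2/mM),
# r the "rate sensitivity" (pmol/m^2/mM), b0 basal secretion
# (pmol/min/m^2) and P(t) a positive time-varying potentiation factor
# normalized to time-average 1 over the record. Plasma C-peptide follows by
# convolving whole-body secretion S = ISR * BSA with the two-compartment
# impulse response h(t) = F exp(-a t) + (1-F) exp(-b t), starting from the
# steady state implied by S(0).

.ogtt_times <- c(0, 15, 30, 45, 60, 90, 120)

# potentiation evaluated on a uniform grid and normalized to mean 1
.pot_curve <- function(t_grid, knots_t, knots_p) {
  if (any(knots_p <= 0)) stop("potentiation knot values must be positive")
  y <- stats::approx(knots_t, knots_p, xout = t_grid, rule = 2)$y
  y / mean(y)
}

# exact-exponential step response of the kinetic layer for piecewise-constant
# input; returns plasma concentration on t_grid (uniform step dt, minutes)
.cp_from_secretion <- function(s_whole, dt, kin) {
  ds <- s_whole - s_whole[1]
  step <- function(rate, frac) {
    dec <- exp(-rate * dt)
    gain <- frac * (1 - dec) / rate
    # trapezoid-average the input over each step
    u <- c(0, (ds[-1] + ds[-length(ds)]) / 2)
    as.numeric(stats::filter(u * gain, dec, method = "recursive"))
  }
  cp_b <- s_whole[1] / (kin$k01 * kin$v_d)
  cp_b + (step(kin$a, kin$frac_fast) + step(kin$b, 1 - kin$frac_fast)) / kin$v_d
}

#' Forward-simulate an OGTT C-peptide curve from beta-cell parameters
#'
#' Integrates the secretion model through two-compartment C-peptide kinetics
#' from basal steady state and samples the solution at the requested times.
#'
#' @param params List with `glucose_sensitivity` (pmol/min/m^2/mM),
#'   `rate_sensitivity` (pmol/m^2/mM), `basal_secretion` (pmol/min/m^2) and
#'   optionally `potentiation`, either a single value 1 (no potentiation) or
#'   a list `list(t = knot times, p = positive knot values)`; knot values
#'   are normalized internally to time-average 1.
#' @param glucose List or data frame with `t_min` and `glucose_mmol_l`
#'   describing the glucose path; interpolated linearly to the dense grid.
#' @param kinetics A [cpeptide_kinetics()] object.
#' @param dt Dense integration step in minutes (default 1).
#' @param t_out Output sample times (default the 7 OGTT times).
#' @return Data frame with `t_min`, `glucose_mmol_l`, `cpeptide_pmol_l`,
#'   plus attributes `isr` (dense secretion curve, pmol/min/m^2) and
#'   `t_grid`.
#' @examples
#' kin <- cpeptide_kinetics(60, "M", 26, "NGM")
#' g <- data.frame(t_min = c(0, 15, 30, 45, 60, 90, 120),
#'                 glucose_mmol_l = c(5.2, 7, 8.2, 8, 7.2, 6, 5.4))
#' forward_simulate_ogtt(list(glucose_sensitivity = 100, rate_sensitivity = 500,
#'                            basal_secretion = 100), g, kin)
#' @export
forward_simulate_ogtt <- function(params, glucose, kinetics, dt = 1,
                                  t_out = .ogtt_times) {
  stopifnot(inherits(kinetics, "cpeptide_kinetics"))
  s <- params$glucose_sensitivity
  r <- params$rate_sensitivity
  b0 <- params$basal_secretion
  if (!all(is.finite(c(s, r, b0)))) stop("invalid beta-cell parameters")
  t_g <- glucose$t_min
  g_v <- glucose$glucose_mmol_l
  if (length(t_g) < 2L) stop("glucose path needs at least two points")
  t_grid <- seq(min(t_g), max(t_g), by = dt)
  G <- stats::approx(t_g, g_v, xout = t_grid, rule = 2)$y
  dG <- c(diff(G) / dt, 0)
  pot <- params$potentiation
  P <- if (is.null(pot) || (is.numeric(pot) && length(pot) == 1L)) {
    rep(1, length(t_grid))
  } else {
    .pot_curve(t_grid, pot$t, pot$p)
  }
  isr <- pmax(0, P * (b0 + s * (G - G[1])) + r * pmax(dG, 0))
  cp <- .cp_from_secretion(isr * kinetics$bsa_m2, dt, kinetics)
  out <- data.frame(
    t_min = t_out,
    glucose_mmol_l = stats::approx(t_g, g_v, xout = t_out, rule = 2)$y,
    cpeptide_pmol_l = stats::approx(t_grid, cp, xout = t_out)$y)
  attr(out, "isr") <- isr
  attr(out, "t_grid") <- t_grid
  attr(out, "cp_dense") <- cp
  out
}

#' Regularized non-negative deconvolution of insulin secretion
#'
#' Recovers the insulin secretion rate on a uniform grid from sampled plasma
#' C-peptide by inverting the two-compartment kinetic layer: minimizes
#' `||predicted CP - observed CP||^2 + lambda * ||D2 ISR||^2 +
#' 0.01 * lambda * ||D1 ISR||^2` subject to ISR >= 0 (Lawson-Hanson
#' non-negative least squares on the penalty-augmented system). The small
#' first-difference term makes the strong-regularization limit a constant
#' secretion rate rather than a sloped line.
#'
#' @param t_min Sample times, minutes (>= 7 samples).
#' @param cp_pmol_l Observed C-peptide, pmol/L.
#' @param kinetics A [cpeptide_kinetics()] object.
#' @param lambda Curvature penalty weight (>= 0), default 100.
#' @param grid_dt Secretion grid step in minutes, default 5.
#' @return Data frame `t_min`, `isr_pmol_min_m2`, with attribute `fitted_cp`
#'   (model C-peptide at the sample times).
#' @export
deconvolve_isr <- function(t_min, cp_pmol_l, kinetics, lambda = 100, grid_dt = 5) {
  stopifnot(inherits(kinetics, "cpeptide_kinetics"))
  if (length(t_min) < 7L) stop("need at least 7 C-peptide samples")
  if (lambda < 0) stop("lambda must be non-negative")
  if (any(cp_pmol_l <= 0)) stop("C-peptide must be positive")
  t0 <- min(t_min)
  edges <- seq(t0, max(t_min), by = grid_dt)
  if (edges[length(edges)] < max(t_min)) edges <- c(edges, max(t_min))
  m <- length(edges) - 1L                      # piecewise-constant ISR cells
  a <- kinetics$a; b <- kinetics$b; f <- kinetics$frac_fast
  # integral of h over [l, u] (times measured backwards from observation)
  H <- function(l, u) f * (exp(-a * l) - exp(-a * u)) / a +
    (1 - f) * (exp(-b * l) - exp(-b * u)) / b
  # steady-state history carried by the first cell's rate
  hist_term <- function(t) f * exp(-a * t) / a + (1 - f) * exp(-b * t) / b
  C <- matrix(0, length(t_min), m)
  for (j in seq_along(t_min)) {
    tj <- t_min[j] - t0
    for (k in seq_len(m)) {
      lo <- edges[k] - t0; hi <- min(edges[k + 1L] - t0, tj)
      if (hi > lo) C[j, k] <- H(tj - hi, tj - lo)
    }
    C[j, 1L] <- C[j, 1L] + hist_term(tj)
  }
  C <- C * kinetics$bsa_m2 / kinetics$v_d
  D2 <- diff(diag(m), differences = 2)
  D1 <- diff(diag(m))
  A <- rbind(C, sqrt(lambda) * D2, sqrt(0.01 * lambda) * D1)
  rhs <- c(cp_pmol_l, rep(0, nrow(D2) + nrow(D1)))
  sol <- pracma::lsqnonneg(A, rhs)
  isr <- sol$x
  out <- data.frame(t_min = (edges[-length(edges)] + edges[-1L]) / 2,
                    isr_pmol_min_m2 = isr)
  attr(out, "fitted_cp") <- as.numeric(C %*% isr)
  attr(out, "edges") <- edges
  out
}
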