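## Forward models: model-free spectral density and amide 15N relaxation
## rates, in solution and under magic-angle spinning (MAS), including the
## near-rotary-resonance spin-lock dependence of R1rho (NERRD).

#' Model-free spectral density
#'
#' `J(omega) = (2/5) * sum_k a_k * tau_k / (1 + (omega * tau_k)^2)` for
#' solids (no overall tumbling). With overall isotropic tumbling (solution),
#' the rigid fraction `S^2 = 1 - sum(a_k)` relaxes with `tau_overall` and
#' each internal component with the combined time
#' `1/tau' = 1/tau_overall + 1/tau_k`.
#'
#' @param model a [motion_model()]
#' @param omega angular frequency in rad/s (vectorized, must be `>= 0`)
#' @return spectral density in seconds, same length as `omega`
#' @export
spectral_density <- function(model, omega) {
  stopifnot(inherits(model, "motion_model"))
  if (any(omega < 0)) stop("omega must be >= 0")
  a <- model$amplitudes
  tau <- model$taus
  if (is.null(model$overall_tau)) {
    if (length(a) == 0) return(rep(0, length(omega)))
    J <- vapply(omega, function(w) {
      J_NORM * sum(a * tau / (1 + (w * tau)^2))
    }, numeric(1))
  } else {
    to <- model$overall_tau
    s2 <- 1 - sum(a)
    tau_eff <- if (length(tau)) 1 / (1 / to + 1 / tau) else numeric()
    J <- vapply(omega, function(w) {
      J_NORM * (s2 * to / (1 + (w * to)^2) +
                  if (length(a)) sum(a * tau_eff / (1 + (w * tau_eff)^2)) else 0)
    }, numeric(1))
  }
  J
}

## Interaction constants bundled for the rate formulas: d (dipolar, rad/s)
## and c (CSA, rad/s) at the condition's field.
.interaction <- function(spin, b0) {
  list(d = dipolar_constant(spin$r_nh), c = csa_constant(spin$csa_delta, b0))
}

#' Longitudinal 15N relaxation rate R1
#'
#' Standard Redfield expression from the 1H-15N dipolar interaction
#' (spectral densities at `omega_H - omega_N`, `omega_N`, `omega_H +
#' omega_N`) plus the 15N CSA term at `omega_N`:
#' `R1 = (d^2/4) * (J(wH-wN) + 3 J(wN) + 6 J(wH+wN)) + c^2 * J(wN)`.
#'
#' @param model a [motion_model()]
#' @param spin a [spin_interaction()]
#' @param cond an [experiment_condition()]; only its field is used
#' @return rate in s^-1
#' @export
r1_rate <- function(model, spin, cond) {
  stopifnot(inherits(spin, "spin_interaction"),
            inherits(cond, "experiment_condition"))
  b0 <- cond$b0
  ic <- .interaction(spin, b0)
  wh <- omega_h(b0); wn <- omega_n(b0)
  Jd <- spectral_density(model, c(abs(wh - wn), wn, wh + wn))
  (ic$d^2 / 4) * (Jd[1] + 3 * Jd[2] + 6 * Jd[3]) + ic$c^2 * Jd[2]
}

## Non-secular ("R1-type") part of on-resonance R1rho; shared between the
## analytic MAS expression and the numerical oracle. Identical to the
## corresponding terms of the static R2 formula; MAS modulation of these
## high-frequency terms is negligible since omega_r << omega_N.
.r1rho_nonsecular <- function(model, spin, b0) {
  ic <- .interaction(spin, b0)
  wh <- omega_h(b0); wn <- omega_n(b0)
  Jd <- spectral_density(model, c(abs(wh - wn), wn, wh, wh + wn))
  (ic$d^2 / 8) * (Jd[1] + 3 * Jd[2] + 6 * Jd[3] + 6 * Jd[4]) +
    (ic$c^2 / 2) * Jd[2]
}

## The near-rotary (secular) spectral-density combination K(nu_1, nu_mas):
## w1*(J(wr-w1)+J(wr+w1)) + w2*(J(2wr-w1)+J(2wr+w1)). In the static limit
## K -> J(0), recovering the 4J(0) term of R2.
.k_nerrd <- function(model, nu_sl, nu_mas) {
  wr <- hz_to_rad(nu_mas); w1 <- hz_to_rad(nu_sl)
  J <- spectral_density(model, abs(c(wr - w1, wr + w1, 2 * wr - w1, 2 * wr + w1)))
  NERRD_W1 * (J[1] + J[2]) + NERRD_W2 * (J[3] + J[4])
}

#' On-resonance 15N R1rho under magic-angle spinning (NERRD forward model)
#'
#' The rate is the sum of high-frequency (R1-type) terms and the secular
#' term whose static `J(0)` weight is redistributed by MAS over spectral
#' densities at the near-rotary combination frequencies
#' `n*omega_r +- omega_1` (n = 1, 2):
#' `R1rho = R_hf + (d^2/2 + 2 c^2/3) * K` with
#' `K = w1*(J(wr-w1) + J(wr+w1)) + w2*(J(2wr-w1) + J(2wr+w1))`,
#' `w1 = 1/3`, `w2 = 1/6` (fixed by calibration against the numerical
#' Redfield oracle, see [redfield_r1rho()]). Motions slower than about 1
#' microsecond make the profile rise as `nu_sl` approaches `nu_mas`
#' (non-flat NERRD profile); for all correlation times below ~100 ns the
#' profile is flat.
#'
#' @inheritParams r1_rate
#' @param cond an [experiment_condition()] with `nu_mas > 0`; the offset is
#'   assumed zero (use [r1rho_offset_correct()] for measured off-resonance
#'   data)
#' @return rate in s^-1
#' @export
r1rho_mas <- function(model, spin, cond) {
  stopifnot(inherits(spin, "spin_interaction"),
            inherits(cond, "experiment_condition"))
  if (cond$nu_mas <= 0)
    stop("nu_mas = 0: use the solution-state path (r2_solution / r1rho with overall tumbling)")
  ic <- .interaction(spin, cond$b0)
  .r1rho_nonsecular(model, spin, cond$b0) +
    (ic$d^2 / 2 + 2 * ic$c^2 / 3) * .k_nerrd(model, cond$nu_sl, cond$nu_mas)
}

#' Solution-state transverse relaxation rate R2
#'
#' Static Redfield R2 for a model with overall tumbling; used for the
#' solution-state (dimer) data path.
#'
#' @inheritParams r1_rate
#' @return rate in s^-1
#' @export
r2_solution <- function(model, spin, cond) {
  stopifnot(inherits(cond, "experiment_condition"))
  if (is.null(model$overall_tau))
    stop("solution-state R2 requires a motion_model with overall_tau")
  ic <- .interaction(spin, cond$b0)
  J0 <- spectral_density(model, 0)
  .r1rho_nonsecular(model, spin, cond$b0) + (ic$d^2 / 2 + 2 * ic$c^2 / 3) * J0
}

#' Offset correction of measured R1rho
#'
#' Removes the longitudinal contribution from an off-resonance spin-lock
#' measurement: with tilt angle `theta = atan2(nu_sl, offset)`, the
#' on-resonance rate is `(R1rho_obs - R1 cos^2(theta)) / sin^2(theta)`.
#'
#' @param r1rho_obs measured rotating-frame rate, s^-1
#' @param r1 longitudinal rate of the same residue, s^-1
#' @param offset resonance offset in Hz
#' @param nu_sl spin-lock nutation frequency in Hz, `> 0`
#' @param tol smallest tolerated `sin^2(theta)`; below it the correction is
#'   numerically unstable and an error is raised
#' @return on-resonance rate in s^-1
#' @export
r1rho_offset_correct <- function(r1rho_obs, r1, offset, nu_sl, tol = 1e-3) {
  if (any(nu_sl <= 0)) stop("nu_sl must be > 0")
  theta <- atan2(nu_sl, offset)
  s2 <- sin(theta)^2
  if (any(s2 < tol))
    stop("offset >> spin-lock: sin^2(theta) below tolerance, correction unstable")
  (r1rho_obs - r1 * cos(theta)^2) / s2
}

#' Transverse 1H-15N dipole/CSA cross-correlated rate eta_xy
#'
#' Forward map used by TRACT: for rigid isotropic tumbling with correlation
#' time `tau_c`,
#' `eta_xy = (sqrt(3)/6) * d * c * P2(cos beta) * (4 J(0) + 3 J(wN))`,
#' where `beta` is the angle between the CSA unique axis and the N-H bond.
#'
#' @param tau_c overall correlation time in seconds
#' @param spin a [spin_interaction()]
#' @return rate in s^-1
#' @export
eta_xy <- function(tau_c, spin) {
  stopifnot(inherits(spin, "spin_interaction"))
  m <- motion_model(overall_tau = tau_c)
  ic <- .interaction(spin, spin$b0)
  J <- spectral_density(m, c(0, omega_n(spin$b0)))
  (sqrt(3) / 6) * ic$d * ic$c * p2(cos(spin$csa_angle * pi / 180)) *
    (4 * J[1] + 3 * J[2])
}

#' Overall correlation time from TRACT rates
#'
#' The difference between the anti-TROSY and TROSY relaxation rates equals
#' twice the transverse dipole/CSA cross-correlated rate,
#' `R_beta - R_alpha = 2 eta_xy(tau_c)`; the map is inverted numerically.
#'
#' @param r_alpha TROSY (slowly relaxing) rate, s^-1
#' @param r_beta anti-TROSY (fast relaxing) rate, s^-1; must exceed `r_alpha`
#' @param spin a [spin_interaction()]
#' @return overall correlation time `tau_c` in seconds
#' @export
tract_tauc <- function(r_alpha, r_beta, spin) {
  if (r_beta <= r_alpha) stop("r_beta must exceed r_alpha")
  target <- (r_beta - r_alpha) / 2
  f <- function(lt) eta_xy(10^lt, spin) - target
  ## eta_xy is monotone in tau_c on the slow-tumbling branch; search ps..0.1ms
  lo <- -13; hi <- -4
  if (f(hi) < 0) stop("rate difference larger than eta_xy at tau_c = 0.1 ms")
  if (f(lo) >= 0) {
    ## below the grid eta_xy is linear in tau_c; return the linear-limit root
    return(1e-13 * target / eta_xy(1e-13, spin))
  }
  10^stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}
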