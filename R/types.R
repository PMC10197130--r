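## Domain types shared across the package: motional models, spin
## interactions and experimental conditions. All are lightweight S3 lists
## with validating constructors.

#' Motional model of an H-N bond vector
#'
#' A sum of independent internal motions, each described by an amplitude
#' `(1 - S^2)` (unitless, `S^2 = 1` for a fully rigid site) and a correlation
#' time `tau` in seconds. For solution-state work an overall isotropic
#' tumbling time `overall_tau` can be given; in solids (MAS) it is absent.
#' Components are stored sorted by increasing `tau` (canonical form).
#'
#' @param amplitudes numeric vector of component amplitudes `(1 - S^2)`,
#'   each in `[0, 1]`, summing to at most 1
#' @param taus numeric vector of correlation times in seconds, all `> 0`
#' @param overall_tau optional overall tumbling correlation time in seconds
#' @return an object of class `motion_model`
#' @examples
#' motion_model(amplitudes = c(0.02, 0.05), taus = c(3e-9, 5e-8))
#' @export
motion_model <- function(amplitudes = numeric(), taus = numeric(),
                         overall_tau = NULL) {
  amplitudes <- as.numeric(amplitudes)
  taus <- as.numeric(taus)
  if (length(amplitudes) != length(taus))
    stop("amplitudes and taus must have equal length")
  if (any(amplitudes < 0 | amplitudes > 1))
    stop("every amplitude (1 - S^2) must lie in [0, 1]")
  if (sum(amplitudes) > 1 + 1e-12)
    stop("sum of amplitudes exceeds 1")
  if (any(taus <= 0)) stop("every tau must be > 0")
  if (!is.null(overall_tau)) {
    overall_tau <- as.numeric(overall_tau)
    if (length(overall_tau) != 1 || overall_tau <= 0)
      stop("overall_tau must be a single positive number")
  }
  ord <- order(taus)
  structure(list(amplitudes = amplitudes[ord], taus = taus[ord],
                 overall_tau = overall_tau),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  cat("<motion_model>\n")
  if (length(x$amplitudes) == 0) cat("  rigid (no internal motion)\n")
  for (k in seq_along(x$amplitudes))
    cat(sprintf("  component %d: 1-S^2 = %.4g, tau = %.4g s\n",
                k, x$amplitudes[k], x$taus[k]))
  if (!is.null(x$overall_tau))
    cat(sprintf("  overall tumbling: tau_c = %.4g s\n", x$overall_tau))
  invisible(x)
}

#' Spin interaction parameters for the amide 1H-15N pair
#'
#' Holds the static magnetic field and the parameters of the two relaxation
#' mechanisms of the amide 15N: the 1H-15N dipolar coupling (bond length
#' `r_nh`) and the 15N chemical-shift anisotropy (`csa_delta`, with
#' `csa_angle` the angle between the CSA unique axis and the N-H bond).
#' Defaults are the standard amide values.
#'
#' @param b0 static field in tesla
#' @param r_nh N-H distance in Angstrom (must be within 0.9-1.2)
#' @param csa_delta 15N CSA in ppm
#' @param csa_angle angle between CSA unique axis and N-H bond, degrees
#' @return an object of class `spin_interaction`
#' @export
spin_interaction <- function(b0 = 14.1, r_nh = 1.02, csa_delta = -172,
                             csa_angle = 0) {
  if (b0 <= 0) stop("b0 must be > 0")
  if (r_nh < 0.9 || r_nh > 1.2) stop("r_nh must be in [0.9, 1.2] Angstrom")
  structure(list(b0 = b0, r_nh = r_nh, csa_delta = csa_delta,
                 csa_angle = csa_angle, pair = "1H-15N"),
            class = "spin_interaction")
}

#' Experimental condition of a relaxation measurement
#'
#' @param b0 static field in tesla
#' @param nu_mas MAS frequency in Hz (0 for solution state)
#' @param nu_sl spin-lock nutation frequency in Hz (0 for longitudinal
#'   relaxation)
#' @param offset resonance offset from the carrier in Hz
#' @param temperature sample temperature in K (metadata only)
#' @param experiment which rate the condition belongs to, `"R1"` or
#'   `"R1rho"`; used when assembling detector sensitivities
#' @return an object of class `experiment_condition`. If `nu_sl >= 2 *
#'   nu_mas` under MAS the condition is outside the regime where the
#'   near-rotary treatment is valid and carries `nerrd_valid = FALSE`.
#' @export
experiment_condition <- function(b0 = 14.1, nu_mas = 0, nu_sl = 0,
                                 offset = 0, temperature = 298,
                                 experiment = c("R1rho", "R1")) {
  experiment <- match.arg(experiment)
  if (nu_mas < 0) stop("nu_mas must be >= 0")
  if (nu_sl < 0) stop("nu_sl must be >= 0")
  nerrd_valid <- !(nu_mas > 0 && nu_sl >= 2 * nu_mas)
  structure(list(b0 = b0, nu_mas = nu_mas, nu_sl = nu_sl, offset = offset,
                 temperature = temperature, experiment = experiment,
                 nerrd_valid = nerrd_valid),
            class = "experiment_condition")
}

#' Compact label identifying a condition (used as RateTable key)
#' @param cond an `experiment_condition`
#' @return a single string
#' @export
condition_key <- function(cond) {
  stopifnot(inherits(cond, "experiment_condition"))
  sprintf("%s_b0=%.4gT_mas=%.5gHz_sl=%.6gHz", cond$experiment, cond$b0,
          cond$nu_mas, cond$nu_sl)
}

#' Two-state chemical exchange model
#'
#' @param p_b minor-state population, in (0, 0.5]
#' @param k_ex exchange rate constant (sum of forward and backward), s^-1
#' @param delta_omega chemical-shift difference between the states, ppm (15N)
#' @param r1 longitudinal rate, s^-1
#' @param r2_0 exchange-free transverse rate (fitted plateau, not
#'   interpreted), s^-1
#' @return an object of class `exchange_model`
#' @export
exchange_model <- function(p_b, k_ex, delta_omega, r1 = 0, r2_0 = 0) {
  if (p_b <= 0 || p_b > 0.5) stop("p_b must lie in (0, 0.5]")
  if (k_ex <= 0) stop("k_ex must be > 0")
  if (r2_0 < 0) stop("r2_0 must be >= 0 (after plateau convention)")
  structure(list(p_b = p_b, k_ex = k_ex, delta_omega = delta_omega,
                 r1 = r1, r2_0 = r2_0),
            class = "exchange_model")
}

## ppm -> rad/s for a 15N shift difference at field b0
ppm_to_rad <- function(ppm, b0) ppm * 1e-6 * omega_n(b0)
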