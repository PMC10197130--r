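## Numerical Redfield evaluation of on-resonance R1rho under simultaneous
## MAS and spin-lock, for a two-site-jump realization of a motional
## component. Serves as the independent oracle against which the sideband
## weights of the analytic r1rho_mas() expression are calibrated, and as a
## cross-check in tests.
##
## Per crystallite the rank-2 spatial tensor of the interaction, expressed
## in the rotor frame, acquires Fourier components at m*omega_r (m = +-1,
## +-2; the m = 0 component vanishes at the magic angle). A two-site jump
## of the bond vector modulates each component with a mono-exponential
## correlation function, so the secular relaxation rate is a sum of
## Lorentzian spectral densities evaluated at m*omega_r - omega_1, weighted
## by the per-crystallite fluctuation amplitudes |Delta A_2m|^2. The powder
## average is taken over a deterministic quasi-uniform spherical grid.

## Quasi-uniform deterministic grid of N directions on the sphere
## (spherical Fibonacci / ZCW-style set); returns an N x 3 matrix.
powder_grid <- function(n) {
  j <- seq_len(n) - 0.5
  z <- 1 - 2 * j / n
  phi <- 2 * pi * j * (1 + sqrt(5)) / 2
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

## Complex rank-2 spherical components sqrt(4pi/5) * Y_2m(u) for unit
## vectors u (rows). Returns an n x 5 complex matrix, columns m = -2..2.
.a2m <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  ep <- complex(real = x, imaginary = y)    # e^{+i phi} sin(theta)
  em <- Conj(ep)
  ## sqrt(4pi/5) Y20 = (3z^2-1)/2; Y2+-1 -> -+ sqrt(3/2) z (x +- iy)/...
  m0 <- (3 * z^2 - 1) / 2
  m1 <- -sqrt(3 / 2) * z * ep
  mm1 <- sqrt(3 / 2) * z * em
  m2 <- sqrt(3 / 8) * ep^2
  mm2 <- sqrt(3 / 8) * em^2
  cbind(`-2` = mm2, `-1` = mm1, `0` = m0, `1` = m1, `2` = m2)
}

## Jump half-angle reproducing amplitude a = 1 - S^2 for a symmetric
## two-site jump with equal populations: S^2 = (1 + 3 cos^2 theta_jump)/4.
.jump_angle <- function(a) {
  if (a > 0.75) stop("two-site jump cannot realize 1-S^2 > 0.75")
  acos(sqrt((3 - 4 * a) / 3))
}

#' Numerical Redfield oracle for on-resonance R1rho under MAS
#'
#' Evaluates second-order relaxation of spin-locked 15N magnetization under
#' simultaneous MAS rotation and a spin-lock, for a two-site-jump
#' realization of each component of `model`, by powder-averaging the
#' Fourier intensities of the MAS-modulated rank-2 spatial functions at the
#' combination frequencies `n*omega_r +- omega_1` (n = 1, 2) weighted by the
#' jump correlation function. High-frequency (R1-type) terms, which are
#' unaffected by MAS, are added analytically. Used to calibrate the
#' sideband weights of [r1rho_mas()].
#'
#' @inheritParams r1_rate
#' @param cond an [experiment_condition()] with `nu_mas > 0`
#' @param powder_points number of crystallite orientations (>= 100)
#' @param check_convergence if `TRUE`, the rate is recomputed on a doubled
#'   grid and an error is raised if it changes by more than 1 percent
#' @return rate in s^-1
#' @export
redfield_r1rho <- function(model, spin, cond, powder_points = 300,
                           check_convergence = FALSE) {
  stopifnot(inherits(model, "motion_model"),
            inherits(spin, "spin_interaction"),
            inherits(cond, "experiment_condition"))
  if (cond$nu_mas <= 0) stop("oracle requires nu_mas > 0")
  if (powder_points < 100) stop("powder_points must be >= 100")

  one_grid <- function(npow) {
    wr <- hz_to_rad(cond$nu_mas); w1 <- hz_to_rad(cond$nu_sl)
    ic <- .interaction(spin, cond$b0)
    weight <- ic$d^2 / 2 + 2 * ic$c^2 / 3
    ## |d^2_{m0}(theta_magic)|^2 for m = -2..2
    dm2 <- c(1 / 6, 1 / 3, 0, 1 / 3, 1 / 6)
    mseq <- -2:2
    u0 <- powder_grid(npow)
    ## deterministic azimuths for the jump plane
    psi <- 2 * pi * (seq_len(npow) * (sqrt(2) %% 1)) %% (2 * pi)
    ## orthonormal tangent at u0 rotated by psi
    ref <- cbind(rep(0, npow), rep(0, npow), rep(1, npow))
    swap <- abs(u0[, 3]) > 0.9
    ref[swap, ] <- matrix(rep(c(1, 0, 0), sum(swap)), ncol = 3, byrow = TRUE)
    t1 <- ref - u0 * rowSums(ref * u0)
    t1 <- t1 / sqrt(rowSums(t1^2))
    t2 <- cbind(u0[, 2] * t1[, 3] - u0[, 3] * t1[, 2],
                u0[, 3] * t1[, 1] - u0[, 1] * t1[, 3],
                u0[, 1] * t1[, 2] - u0[, 2] * t1[, 1])
    tt <- t1 * cos(psi) + t2 * sin(psi)
    rate <- 0
    for (k in seq_along(model$amplitudes)) {
      a <- model$amplitudes[k]; tau <- model$taus[k]
      if (a == 0) next
      th <- .jump_angle(a) / 2   # sites sit at +- half the jump angle
      u1 <- u0 * cos(th) + tt * sin(th)
      u2 <- u0 * cos(th) - tt * sin(th)
      dA <- .a2m(u1) - .a2m(u2)
      amp <- 0.25 * Mod(dA)^2          # p1 p2 |Delta A_2m|^2, p = 1/2
      lor <- tau / (1 + ((mseq * wr - w1) * tau)^2)
      ## factor 5: single-m correlation vs the total (sum over m)
      ## correlation function that defines the J(0) convention
      contrib <- 5 * J_NORM * (amp %*% (dm2 * lor))
      rate <- rate + weight * mean(contrib)
    }
    rate + .r1rho_nonsecular(model, spin, cond$b0)
  }

  r <- one_grid(powder_points)
  if (check_convergence) {
    r2 <- one_grid(2 * powder_points)
    if (abs(r2 - r) > 0.01 * max(abs(r), 1e-12))
      stop("powder average not converged: rate changes > 1% on grid doubling")
  }
  r
}

#' Recalibrate the NERRD sideband weights against the numerical oracle
#'
#' Least-squares fit of the two sideband weights `(w1, w2)` of the analytic
#' secular term of [r1rho_mas()] to oracle rates computed over a grid of
#' correlation times and spin-lock strengths. The package's frozen
#' constants are `w1 = 1/3`, `w2 = 1/6`; this function documents their
#' provenance and is exercised by a test.
#'
#' @param spin a [spin_interaction()]
#' @param nu_mas MAS frequency in Hz
#' @param taus correlation times (s) of the calibration grid
#' @param nu_sls spin-lock strengths (Hz) of the calibration grid
#' @param amplitude motional amplitude used for the calibration motions
#' @param powder_points crystallites per oracle evaluation
#' @return named numeric vector `c(w1, w2)`
#' @export
calibrate_sideband_weights <- function(spin = spin_interaction(),
                                       nu_mas = 45e3,
                                       taus = c(1e-6, 5e-6, 2e-5, 1e-4),
                                       nu_sls = c(5e3, 15e3, 25e3, 35e3, 41e3),
                                       amplitude = 0.05,
                                       powder_points = 400) {
  grid <- expand.grid(tau = taus, nu_sl = nu_sls)
  rows <- t(apply(grid, 1, function(g) {
    m <- motion_model(amplitude, g[["tau"]])
    cond <- experiment_condition(b0 = spin$b0, nu_mas = nu_mas,
                                 nu_sl = g[["nu_sl"]])
    ic <- .interaction(spin, spin$b0)
    wgt <- ic$d^2 / 2 + 2 * ic$c^2 / 3
    wr <- hz_to_rad(nu_mas); w1 <- hz_to_rad(g[["nu_sl"]])
    J <- spectral_density(m, abs(c(wr - w1, wr + w1, 2 * wr - w1, 2 * wr + w1)))
    y <- redfield_r1rho(m, spin, cond, powder_points) -
      .r1rho_nonsecular(m, spin, spin$b0)
    c(x1 = wgt * (J[1] + J[2]), x2 = wgt * (J[3] + J[4]), y = y)
  }))
  fit <- stats::lm.fit(rows[, c("x1", "x2")], rows[, "y"])
  w <- fit$coefficients
  names(w) <- c("w1", "w2")
  w
}
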