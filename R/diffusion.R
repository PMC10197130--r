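## Translational diffusion from gradient-encoded (DOSY) decays, viscosity
## and temperature normalization, and the two-state decamer-dimer
## transition fit along temperature.

#' Gradient-encoded diffusion decay series
#'
#' @param temperature sample temperature in K
#' @param g gradient strengths in T/m, non-negative increasing
#' @param intensities integrated signal intensities
#' @param intensity_errs optional uncertainties
#' @param delta_grad gradient duration in s (bipolar pair total; reference
#'   design 3.2 ms)
#' @param delta_big diffusion delay in s (reference design 400 ms)
#' @param tau_gap bipolar gradient gap in s (reference design 0.1 ms)
#' @return an object of class `dosy_series`
#' @export
dosy_series <- function(temperature, g, intensities, intensity_errs = NULL,
                        delta_grad = 3.2e-3, delta_big = 0.4,
                        tau_gap = 1e-4) {
  if (any(g < 0) || any(diff(g) <= 0))
    stop("g must be non-negative and increasing")
  if (length(intensities) != length(g)) stop("intensities must match g")
  structure(list(temperature = temperature, g = as.numeric(g),
                 intensities = as.numeric(intensities),
                 intensity_errs = intensity_errs,
                 delta_grad = delta_grad, delta_big = delta_big,
                 tau_gap = tau_gap),
            class = "dosy_series")
}

## Stejskal-Tanner b-factor with bipolar correction:
## b(g) = gamma_H^2 g^2 delta^2 (Delta - delta/3 - tau/2)
.st_b <- function(series) {
  .const$gamma_h^2 * series$g^2 * series$delta_grad^2 *
    (series$delta_big - series$delta_grad / 3 - series$tau_gap / 2)
}

#' Fit a translational diffusion coefficient from a DOSY decay
#'
#' Stejskal-Tanner with bipolar correction:
#' `I(g) = I0 * exp(-D * gamma_H^2 g^2 delta^2 (Delta - delta/3 - tau/2))`.
#' Monte-Carlo uncertainties; a non-monotone decay beyond the noise level is
#' flagged.
#'
#' @param series a [dosy_series()] with >= 5 gradient points
#' @param n_mc Monte-Carlo draws
#' @param seed RNG seed
#' @return list with `D` (m^2/s), `D_err`, `i0`, `red_chi2`, `flags`
#' @export
fit_diffusion <- function(series, n_mc = 100, seed = 1L) {
  stopifnot(inherits(series, "dosy_series"))
  if (length(series$g) < 5) stop("need >= 5 gradient points")
  b <- .st_b(series)
  y <- series$intensities
  ## same profile trick as the exponential decay fit: I0 linear given D
  sig <- series$intensity_errs
  w <- if (is.null(sig)) rep(1, length(y)) else 1 / sig^2
  core <- function(yy) {
    prof <- function(d) {
      e <- exp(-d * b)
      i0 <- sum(w * yy * e) / sum(w * e^2)
      sum(w * (yy - i0 * e)^2)
    }
    dmax <- 20 / max(b)
    opt <- stats::optimize(prof, c(0, dmax), tol = dmax * 1e-12)
    e <- exp(-opt$minimum * b)
    list(D = opt$minimum, i0 = sum(w * yy * e) / sum(w * e^2))
  }
  fit <- core(y)
  resid <- y - fit$i0 * exp(-fit$D * b)
  if (is.null(sig)) {
    s <- stats::sd(resid) * sqrt(length(y) / max(length(y) - 2, 1))
    sig <- rep(max(s, 1e-12 * max(abs(y))), length(y))
  }
  flags <- character()
  ## non-monotone decay beyond noise
  inc <- diff(y)
  if (any(inc > 3 * sig[-1])) flags <- c(flags, "non_monotone")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ideal <- fit$i0 * exp(-fit$D * b)
  draws <- vapply(seq_len(n_mc), function(i)
    core(ideal + stats::rnorm(length(y), 0, sig))$D, numeric(1))
  dof <- max(length(y) - 2, 1)
  list(D = fit$D, D_err = stats::sd(draws), i0 = fit$i0,
       red_chi2 = sum((resid / sig)^2) / dof, flags = flags)
}

#' Viscosity of D2O-based buffer versus temperature
#'
#' Tabulated dynamic viscosity of heavy water (mPa s) over 275-345 K,
#' following the standard temperature correlation for D2O (cf. Cho et al.,
#' J. Phys. Chem. B 103 (1999) 1991). Interpolation between tabulated
#' temperatures is linear in `log(eta)`.
#'
#' @return data frame with columns `temperature` (K) and `eta` (mPa s)
#' @export
d2o_viscosity_table <- function() {
  data.frame(
    temperature = c(275, 280, 285, 290, 295, 298, 300, 305, 310, 315,
                    320, 325, 330, 335, 340, 345),
    eta = c(2.355, 1.999, 1.725, 1.507, 1.331, 1.240, 1.186, 1.065,
            0.963, 0.878, 0.804, 0.741, 0.687, 0.639, 0.597, 0.560))
}

#' Normalize a diffusion coefficient for viscosity and temperature
#'
#' Stokes-Einstein normalization to a reference temperature so that only
#' hydrodynamic-size changes remain:
#' `D_norm = D * (eta(T)/eta(T_ref)) * (T_ref / T)`.
#'
#' @param D diffusion coefficient(s) in m^2/s
#' @param temperature measurement temperature(s) in K
#' @param t_ref reference temperature in K
#' @param viscosity table with columns `temperature` (K), `eta` (mPa s);
#'   temperatures outside the table raise an error
#' @return normalized diffusion coefficient(s)
#' @export
viscosity_normalize <- function(D, temperature, t_ref = 298,
                                viscosity = d2o_viscosity_table()) {
  eta_at <- function(tk) {
    if (any(tk < min(viscosity$temperature) | tk > max(viscosity$temperature)))
      stop("temperature outside the viscosity table range")
    exp(stats::approx(viscosity$temperature, log(viscosity$eta), tk)$y)
  }
  D * (eta_at(temperature) / eta_at(t_ref)) * (t_ref / temperature)
}

#' Two-state oligomer-transition fit of normalized diffusion vs temperature
#'
#' Population-weighted fast-exchange model
#' `D(T) = p(T) * D_oligomer + (1 - p(T)) * D_dissociated` with a two-state
#' van 't Hoff sigmoid
#' `p(T) = 1 / (1 + exp((dH/R) (1/T_mid - 1/T)))`,
#' where `p` is the fraction of the large (slow-diffusing) species.
#' Returns the midpoint `T_mid` where `p = 0.5`.
#'
#' @param temperature temperatures in K (>= 6, spanning the transition)
#' @param d_norm viscosity/temperature-normalized diffusion coefficients
#' @param d_errs optional uncertainties on `d_norm`
#' @param d_oligomer,d_dissociated reference diffusion coefficients of the
#'   pure states (m^2/s); `NULL` to co-fit (requires plateaus at both ends)
#' @return list with `t_mid`, `t_mid_err`, `dh` (van 't Hoff enthalpy,
#'   J/mol), `d_oligomer`, `d_dissociated`, `populations` (data frame),
#'   `flags` (`"extrapolated_midpoint"` when `t_mid` is outside the sampled
#'   range, `"no_transition"` when the data are flat)
#' @export
fit_transition <- function(temperature, d_norm, d_errs = NULL,
                           d_oligomer = NULL, d_dissociated = NULL) {
  if (length(temperature) < 6) stop("need >= 6 temperatures")
  if (is.null(d_errs)) d_errs <- rep(stats::sd(d_norm) * 0.05 + 1e-18,
                                     length(d_norm))
  flags <- character()
  span <- diff(range(d_norm))
  ## a series is transition-free when its spread is within noise or small
  ## against the separation of the pure-state coefficients
  ref_gap <- if (!is.null(d_oligomer) && !is.null(d_dissociated))
    abs(d_oligomer - d_dissociated) else Inf
  if (span < 3 * mean(d_errs) || span < 0.05 * ref_gap)
    flags <- c(flags, "no_transition")
  cofit <- is.null(d_oligomer) || is.null(d_dissociated)
  pfun <- function(tmid, dh) 1 / (1 + exp((dh / .const$gas_r) *
                                            (1 / tmid - 1 / temperature)))
  resid_fn <- function(par) {
    tmid <- par[1]; dh <- par[2]
    dol <- if (cofit) par[3] else d_oligomer
    ddi <- if (cofit) par[4] else d_dissociated
    p <- pfun(tmid, dh)
    (p * dol + (1 - p) * ddi - d_norm) / d_errs
  }
  ## multi-start over the sign of the van 't Hoff slope so that swapping
  ## the state labels (p <-> 1 - p) converges to the same solution
  fit <- NULL
  for (dh0 in c(3e5, -3e5)) {
    p0 <- c(stats::median(temperature), dh0,
            if (cofit) c(min(d_norm), max(d_norm)))
    f <- minpack.lm::nls.lm(p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
    if (is.null(fit) || sum(f$fvec^2) < sum(fit$fvec^2)) fit <- f
  }
  par <- fit$par
  dof <- max(length(d_norm) - length(par), 1)
  covm <- tryCatch(solve(fit$hessian) * 2 * sum(fit$fvec^2) / dof,
                   error = function(e) matrix(NA, length(par), length(par)))
  if (par[1] < min(temperature) || par[1] > max(temperature))
    flags <- c(flags, "extrapolated_midpoint")
  p <- pfun(par[1], par[2])
  list(t_mid = par[1], t_mid_err = sqrt(abs(covm[1, 1])), dh = par[2],
       d_oligomer = if (cofit) par[3] else d_oligomer,
       d_dissociated = if (cofit) par[4] else d_dissociated,
       populations = data.frame(temperature = temperature, p_oligomer = p),
       flags = flags)
}
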