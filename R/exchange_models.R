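## Two-state chemical-exchange contributions to R1rho: the fast-exchange
## closed form, the Laguerre (Miloushev-Palmer) general-regime
## approximation, and a numerical Bloch-McConnell propagator that serves as
## the ground truth for both.

#' Relaxation-dispersion curve of one residue
#'
#' @param residue residue identifier (integer or string)
#' @param nu_sl spin-lock strengths in Hz, strictly increasing
#' @param rates R1rho rate constants, s^-1
#' @param rate_errs rate uncertainties, s^-1
#' @param corrected `TRUE` if the rates have been NERRD-corrected
#' @return an object of class `dispersion_curve`
#' @export
dispersion_curve <- function(residue, nu_sl, rates, rate_errs = NULL,
                             corrected = FALSE) {
  if (is.null(rate_errs)) rate_errs <- rep(NA_real_, length(rates))
  if (length(nu_sl) != length(rates) || length(rates) != length(rate_errs))
    stop("nu_sl, rates and rate_errs must have equal length")
  if (any(diff(nu_sl) <= 0)) stop("nu_sl must be strictly increasing")
  structure(list(residue = residue, nu_sl = as.numeric(nu_sl),
                 rates = as.numeric(rates), rate_errs = as.numeric(rate_errs),
                 corrected = isTRUE(corrected)),
            class = "dispersion_curve")
}

#' Fast-exchange R1rho exchange contribution
#'
#' `R_ex = pA * pB * dw^2 * k_ex / (k_ex^2 + w1^2)` with the shift
#' difference in rad/s; the spin-lock quenches the exchange broadening as
#' `w1` grows. Returns `r2_0 + R_ex` (the caller handles any R1/offset
#' contribution).
#'
#' @param model an [exchange_model()]
#' @param nu_sl spin-lock strength in Hz (vectorized)
#' @param b0 static field in tesla
#' @return rate in s^-1
#' @export
rex_fast_exchange <- function(model, nu_sl, b0) {
  stopifnot(inherits(model, "exchange_model"))
  w1 <- hz_to_rad(nu_sl)
  dw <- ppm_to_rad(model$delta_omega, b0)
  pa <- 1 - model$p_b
  model$r2_0 + pa * model$p_b * dw^2 * model$k_ex / (model$k_ex^2 + w1^2)
}

#' Laguerre (Miloushev-Palmer) approximation for R1rho with two-state exchange
#'
#' General-regime second-order approximation for off- or on-resonance R1rho
#' under a spin-lock with two-state exchange. With the carrier at the
#' population-average shift, state offsets are `OmegaA = offset_rad - pB*dw`
#' and `OmegaB = offset_rad + pA*dw`. Reduces to [rex_fast_exchange()]
#' (plus the `cos^2(theta) R1` term) in the fast-exchange limit
#' `k_ex >> dw`.
#'
#' @inheritParams rex_fast_exchange
#' @param offset carrier offset in Hz
#' @return rate in s^-1, with attribute `approx_valid = FALSE` when
#'   `p_b > 0.3` and the exchange is slow (`k_ex < dw` in rad/s)
#' @export
r1rho_laguerre <- function(model, nu_sl, offset = 0, b0 = 14.1) {
  stopifnot(inherits(model, "exchange_model"))
  w1 <- hz_to_rad(nu_sl)
  dw <- ppm_to_rad(model$delta_omega, b0)
  pa <- 1 - model$p_b; pb <- model$p_b
  om <- hz_to_rad(offset)
  oa <- om - pb * dw
  ob <- om + pa * dw
  obar <- pa * oa + pb * ob            # equals om
  we2 <- w1^2 + obar^2
  wea2 <- w1^2 + oa^2
  web2 <- w1^2 + ob^2
  s2t <- w1^2 / we2
  c2t <- 1 - s2t
  phi <- pa * pb * dw^2
  kex <- model$k_ex
  denom <- wea2 * web2 / we2 + kex^2 -
    s2t * phi * (1 + 2 * kex^2 * (pa * wea2 + pb * web2) /
                   (wea2 * web2 + we2 * kex^2))
  rate <- c2t * model$r1 + s2t * model$r2_0 + s2t * phi * kex / denom
  attr(rate, "approx_valid") <- !(pb > 0.3 && kex < abs(dw))
  rate
}

## Internal Bloch-McConnell rate with explicit populations (allows the
## state-relabeling symmetry check). Basis (MxA,MyA,MzA,MxB,MyB,MzB).
.bm_rate <- function(pa, pb, dw_rad, kex, r1, r2, nu_sl, offset, lock_time,
                     n_t = 64, resid_tol = 1e-3) {
  w1 <- hz_to_rad(nu_sl)
  om <- hz_to_rad(offset)
  oa <- om - pb * dw_rad
  ob <- om + pa * dw_rad
  blk <- function(o) matrix(c(-r2,  o,   0,
                              -o,  -r2,  w1,
                               0,  -w1, -r1), 3, 3, byrow = TRUE)
  kab <- pb * kex; kba <- pa * kex
  L <- matrix(0, 6, 6)
  L[1:3, 1:3] <- blk(oa) - kab * diag(3)
  L[4:6, 4:6] <- blk(ob) - kba * diag(3)
  L[1:3, 4:6] <- kba * diag(3)
  L[4:6, 1:3] <- kab * diag(3)
  theta <- atan2(w1, om)
  e <- c(sin(theta), 0, cos(theta))
  m0 <- c(pa * e, pb * e)
  ev <- eigen(L)
  ci <- solve(ev$vectors, m0)
  tt <- seq(0, lock_time, length.out = n_t)[-1]
  mt <- ev$vectors %*% (ci * exp(outer(ev$values, tt)))
  proj <- Re(crossprod(c(e, e), mt))[1, ]
  ## rate from the final 80% of the lock, avoiding initial transients
  keep <- tt >= 0.2 * lock_time
  if (any(proj[keep] <= 0))
    stop("projected magnetization non-positive; lock_time too long for this rate")
  fit <- stats::lm(log(proj[keep]) ~ tt[keep])
  rate <- -unname(stats::coef(fit)[2])
  rel_resid <- sqrt(mean(stats::residuals(fit)^2))
  structure(rate, mono_exponential = rel_resid < resid_tol)
}

#' Bloch-McConnell propagator oracle for R1rho with two-state exchange
#'
#' Builds the 6x6 two-state evolution generator for the x, y, z
#' magnetization of each state, including exchange, relaxation, offsets and
#' the spin-lock, propagates it by eigendecomposition, projects onto the
#' effective-field axis, and extracts the decay rate by a linear fit of the
#' log-projection over the final 80 percent of the lock. Deterministic; the
#' ground truth for [rex_fast_exchange()] and [r1rho_laguerre()].
#'
#' @inheritParams r1rho_laguerre
#' @param lock_time spin-lock duration in s; should be at least `5 / k_ex`
#'   for a mono-exponential regime
#' @return rate in s^-1, with attribute `mono_exponential` (`FALSE` flags a
#'   decay whose log-linear fit residual exceeds tolerance)
#' @export
bm_propagator_oracle <- function(model, nu_sl, offset = 0, b0 = 14.1,
                                 lock_time = NULL) {
  stopifnot(inherits(model, "exchange_model"))
  if (is.null(lock_time)) lock_time <- max(5 / model$k_ex, 0.02)
  .bm_rate(1 - model$p_b, model$p_b, ppm_to_rad(model$delta_omega, b0),
           model$k_ex, model$r1, model$r2_0, nu_sl, offset, lock_time)
}

#' Joint two-state exchange fit of multiple dispersion curves
#'
#' Shared-parameter nonlinear least squares: `k_ex` is global (and
#' optionally `p_b`); the shift difference `delta_omega` and the plateau
#' `r2_0` are per residue. The plateau is fitted and not interpreted.
#' Initialization is multi-start over log-spaced `k_ex` values; parameter
#' uncertainties come from the covariance matrix and optionally from
#' Monte-Carlo resampling of the rate errors.
#'
#' @param curves list of [dispersion_curve()] objects (>= 2 unless a single
#'   independent fit is wanted), each with >= 4 spin-lock points
#' @param b0 static field in tesla
#' @param shared character vector, `c("k_ex")` or `c("k_ex", "p_b")`
#' @param p_b fixed minor-state population when not shared/fitted
#' @param kex_starts multi-start initial values for `k_ex` (s^-1)
#' @param n_mc Monte-Carlo resampling draws for uncertainties (0 to skip)
#' @param seed RNG seed for the Monte-Carlo draws
#' @return a list with elements `k_ex`, `k_ex_err`, `p_b`, `per_residue`
#'   (data frame with `residue`, `delta_omega`, `delta_omega_err`, `r2_0`),
#'   `diagnostics` (SSR, reduced chi-square, convergence), and `k_ex_mc`
#'   (MC draws) when `n_mc > 0`
#' @export
fit_dispersion_joint <- function(curves, b0 = 14.1, shared = "k_ex",
                                 p_b = 0.05,
                                 kex_starts = 10^seq(2, 5, length.out = 8),
                                 n_mc = 0, seed = 1L) {
  if (inherits(curves, "dispersion_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, "dispersion_curve")))
  if (any(vapply(curves, function(cv) length(cv$nu_sl), 1L) < 4))
    stop("each curve needs >= 4 spin-lock points")
  fit_pb <- "p_b" %in% shared
  nc <- length(curves)
  nu <- lapply(curves, `[[`, "nu_sl")
  y <- unlist(lapply(curves, `[[`, "rates"))
  err <- unlist(lapply(curves, `[[`, "rate_errs"))
  err[!is.finite(err) | err <= 0] <- stats::median(err[is.finite(err) & err > 0],
                                                   na.rm = TRUE)
  if (all(is.na(err))) err <- rep(1, length(y))

  unpack <- function(p) {
    kex <- 10^p[1]
    pb <- if (fit_pb) stats::plogis(p[2]) / 2 else p_b
    off <- if (fit_pb) 2 else 1
    dw <- abs(p[off + seq_len(nc)])
    r20 <- p[off + nc + seq_len(nc)]
    list(kex = kex, pb = pb, dw = dw, r20 = r20)
  }
  resid_fn <- function(p) {
    q <- unpack(p)
    pred <- unlist(lapply(seq_len(nc), function(i) {
      em <- exchange_model(p_b = q$pb, k_ex = q$kex, delta_omega = q$dw[i],
                           r2_0 = max(q$r20[i], 0))
      as.numeric(r1rho_laguerre(em, nu[[i]], offset = 0, b0 = b0)) +
        min(q$r20[i], 0)  # allow a plateau below zero without invalidating the model
    }))
    (pred - y) / err
  }

  best <- NULL
  for (k0 in kex_starts) {
    p0 <- c(log10(k0), if (fit_pb) stats::qlogis(min(2 * p_b, 0.99)),
            rep(2, nc), vapply(curves, function(cv) min(cv$rates), 1))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    stop("joint dispersion fit failed to converge from all starts")

  fit <- best$fit
  q <- unpack(fit$par)
  dof <- max(length(y) - length(fit$par), 1)
  covm <- tryCatch(solve(fit$hessian) * 2 * best$ssr / dof,
                   error = function(e) matrix(NA, length(fit$par), length(fit$par)))
  kex_err <- abs(log(10) * q$kex) * sqrt(abs(covm[1, 1]))
  off <- if (fit_pb) 2 else 1
  dw_err <- sqrt(abs(diag(covm)[off + seq_len(nc)]))

  kex_mc <- NULL
  if (n_mc > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    kex_mc <- vapply(seq_len(n_mc), function(i) {
      yi <- stats::rnorm(length(y), unlist(lapply(seq_len(nc), function(j) {
        em <- exchange_model(q$pb, q$kex, q$dw[j], r2_0 = max(q$r20[j], 0))
        as.numeric(r1rho_laguerre(em, nu[[j]], 0, b0)) + min(q$r20[j], 0)
      })), err)
      resid_mc <- function(p) {
        qq <- unpack(p)
        pred <- unlist(lapply(seq_len(nc), function(j) {
          em <- exchange_model(qq$pb, qq$kex, qq$dw[j], r2_0 = max(qq$r20[j], 0))
          as.numeric(r1rho_laguerre(em, nu[[j]], 0, b0)) + min(qq$r20[j], 0)
        }))
        (pred - yi) / err
      }
      f <- tryCatch(minpack.lm::nls.lm(fit$par, fn = resid_mc,
                                       control = minpack.lm::nls.lm.control(maxiter = 150)),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else 10^f$par[1]
    }, numeric(1))
  }

  list(k_ex = q$kex, k_ex_err = kex_err, p_b = q$pb,
       per_residue = data.frame(
         residue = vapply(curves, function(cv) as.character(cv$residue), ""),
         delta_omega = q$dw, delta_omega_err = dw_err, r2_0 = q$r20,
         stringsAsFactors = FALSE),
       diagnostics = list(ssr = best$ssr,
                          red_chi2 = best$ssr / dof,
                          info = fit$info, message = fit$message),
       k_ex_mc = kex_mc)
}

## Save/restore the global RNG state so seeded internals do not disturb the
## caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
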