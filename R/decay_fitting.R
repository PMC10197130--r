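## Turning raw peak-intensity series into rate constants with
## uncertainties, plus the intensity-normalization, 1-2-1 smoothing and
## dispersion-significance conventions used downstream.

#' Peak-intensity decay series of one residue
#'
#' @param residue residue identifier
#' @param delays relaxation delays in seconds, non-negative and strictly
#'   increasing, at least 3
#' @param intensities peak intensities (arbitrary units)
#' @param intensity_errs optional intensity uncertainties; when absent they
#'   are estimated from the residuals of a first-pass fit
#' @param condition an [experiment_condition()]
#' @return an object of class `decay_series`
#' @export
decay_series <- function(residue, delays, intensities, intensity_errs = NULL,
                         condition = experiment_condition()) {
  if (length(delays) < 3) stop("need >= 3 delay points")
  if (any(delays < 0) || any(diff(delays) <= 0))
    stop("delays must be non-negative and strictly increasing")
  if (length(intensities) != length(delays))
    stop("intensities and delays must have equal length")
  if (!is.null(intensity_errs) && length(intensity_errs) != length(delays))
    stop("intensity_errs must match delays")
  structure(list(residue = residue, delays = as.numeric(delays),
                 intensities = as.numeric(intensities),
                 intensity_errs = if (is.null(intensity_errs)) NULL
                                  else as.numeric(intensity_errs),
                 condition = condition),
            class = "decay_series")
}

## Weighted mono-exponential fit I(t) = I0 exp(-R t). For fixed R the
## amplitude is linear, so the profile objective is one-dimensional in R;
## minimized with optimize() after a log-linear starting bracket.
.expfit_core <- function(t, y, w) {
  prof <- function(r) {
    e <- exp(-r * t)
    i0 <- sum(w * y * e) / sum(w * e^2)
    list(ssr = sum(w * (y - i0 * e)^2), i0 = i0)
  }
  ## bracket: log-linear slope from positive intensities, else 0
  pos <- y > 0
  r0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2]
    max(-sl, 0)
  } else 0
  span <- max(r0 * 20, 10 / max(t[t > 0], 1e-9))
  opt <- stats::optimize(function(r) prof(r)$ssr, c(-0.2 * span, span),
                         tol = max(span * 1e-10, 1e-12))
  res <- prof(opt$minimum)
  list(rate = opt$minimum, i0 = res$i0, ssr = res$ssr)
}

#' Fit a mono-exponential decay
#'
#' Weighted least-squares fit of `I(t) = I0 * exp(-R t)` with rate
#' uncertainty from Monte-Carlo noise resampling. Negative intensities are
#' retained (noise can drive them below zero), so the fit is nonlinear
#' rather than log-linear. When the series carries no intensity errors the
#' noise level is estimated from the residuals of a first-pass fit.
#'
#' @param series a [decay_series()]
#' @param n_mc number of Monte-Carlo draws for the rate uncertainty
#' @param seed RNG seed for the resampling
#' @return list with `rate`, `rate_err`, `amplitude`, `red_chi2`,
#'   `residuals` and `flags` (character vector; `"zero_rate"` for an
#'   all-equal series, `"negative_rate"` when the fitted rate is negative)
#' @export
fit_monoexponential <- function(series, n_mc = 100, seed = 1L) {
  stopifnot(inherits(series, "decay_series"))
  t <- series$delays; y <- series$intensities
  flags <- character()
  if (length(unique(y)) == 1L) {
    return(list(rate = 0, rate_err = 0, amplitude = y[1], red_chi2 = 0,
                residuals = rep(0, length(y)), flags = "zero_rate"))
  }
  sig <- series$intensity_errs
  if (!is.null(sig) && any(!is.finite(sig) | sig <= 0)) sig <- NULL
  w <- if (is.null(sig)) rep(1, length(y)) else 1 / sig^2
  fit <- .expfit_core(t, y, w)
  resid <- y - fit$i0 * exp(-fit$rate * t)
  if (is.null(sig)) {
    s <- stats::sd(resid) * sqrt(length(y) / max(length(y) - 2, 1))
    sig <- rep(max(s, 1e-12 * max(abs(y))), length(y))
    w <- 1 / sig^2
    fit <- .expfit_core(t, y, w)
    resid <- y - fit$i0 * exp(-fit$rate * t)
  }
  dof <- max(length(y) - 2, 1)
  red_chi2 <- sum((resid / sig)^2) / dof
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ideal <- fit$i0 * exp(-fit$rate * t)
  draws <- vapply(seq_len(n_mc), function(i) {
    .expfit_core(t, ideal + stats::rnorm(length(t), 0, sig), w)$rate
  }, numeric(1))
  if (fit$rate < 0) flags <- c(flags, "negative_rate")
  list(rate = fit$rate, rate_err = stats::sd(draws), amplitude = fit$i0,
       red_chi2 = red_chi2, residuals = resid, flags = flags)
}

#' Normalize peak intensities across experiments
#'
#' Rescales intensities for differences in the 1H 90-degree pulse length,
#' the number of scans, and the dilution factor between a series and its
#' reference: signal is proportional to the number of scans and to the
#' concentration, and inversely proportional to the pulse length (probe
#' loading), so
#' `corrected = raw * (pulse_obs/pulse_ref) / (scans_obs/scans_ref) *
#'  (dilution_obs/dilution_ref)`.
#'
#' @param raw intensity vector
#' @param pulse_90_us length-2 vector `c(observed, reference)` 1H-90 pulse
#'   lengths in microseconds
#' @param n_scans length-2 vector `c(observed, reference)` scan counts
#' @param dilution length-2 vector `c(observed, reference)` dilution factors
#' @return corrected intensities
#' @export
normalize_intensities <- function(raw, pulse_90_us = c(1, 1),
                                  n_scans = c(1, 1), dilution = c(1, 1)) {
  for (v in list(pulse_90_us, n_scans, dilution)) {
    if (length(v) != 2 || any(v <= 0))
      stop("correction factors must be positive pairs (observed, reference)")
  }
  raw * (pulse_90_us[1] / pulse_90_us[2]) *
    (n_scans[2] / n_scans[1]) *
    (dilution[1] / dilution[2])
}

#' 1-2-1 smoothing along the sequence
#'
#' Replaces the value at residue i by the weighted mean of (i-1, i, i+1)
#' with weights 1-2-1; missing neighbors (gaps, chain ends) drop out of
#' both numerator and denominator, and gaps stay gaps.
#'
#' @param values numeric vector indexed by residue number (`NA` = gap)
#' @return smoothed vector of the same length
#' @export
smooth_121 <- function(values) {
  n <- length(values)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(values[i])) next
    v <- c(if (i > 1) values[i - 1] else NA, values[i],
           if (i < n) values[i + 1] else NA)
    wts <- c(1, 2, 1)[!is.na(v)]
    out[i] <- sum(v[!is.na(v)] * wts) / sum(wts)
  }
  out
}

#' Flag residues with significant relaxation dispersion
#'
#' Computes the per-residue difference `Delta R1rho = R(low spin-lock) -
#' R(high spin-lock)` and flags residues whose difference exceeds three
#' times the standard deviation of the differences over all residues (the
#' population SD, computed including any flagged residues; no iterative
#' trimming).
#'
#' @param low_rate,high_rate rate tables (see [rate_table()]) at the low
#'   and high spin-lock strengths, with matching residue sets
#' @return list with `flagged` (residue ids above threshold), `threshold`
#'   (s^-1), and `delta` (data frame residue/delta)
#' @export
dispersion_significance <- function(low_rate, high_rate) {
  m <- merge(low_rate[, c("residue", "rate")],
             high_rate[, c("residue", "rate")],
             by = "residue", suffixes = c("_low", "_high"))
  if (nrow(m) < 5) stop("need >= 5 residues for a stable SD")
  delta <- m$rate_low - m$rate_high
  thr <- 3 * stats::sd(delta)
  list(flagged = m$residue[delta > thr], threshold = thr,
       delta = data.frame(residue = m$residue, delta = delta))
}

#' Construct a rate table
#'
#' The interchange currency between pipeline stages: one row per (residue,
#' condition) with a rate constant and its uncertainty.
#'
#' @param residue,rate,rate_err,condition vectors of equal length
#'   (`condition` holds [condition_key()] strings)
#' @param experiment free-text provenance label
#' @param corrected whether rates have been NERRD-corrected
#' @return a data frame of class `rate_table`
#' @export
rate_table <- function(residue, rate, rate_err, condition,
                       experiment = "", corrected = FALSE) {
  df <- data.frame(residue = residue, rate = rate, rate_err = rate_err,
                   condition = condition, stringsAsFactors = FALSE)
  if (any(df$rate_err < 0, na.rm = TRUE)) stop("rate errors must be >= 0")
  if (anyDuplicated(df[, c("residue", "condition")]))
    stop("duplicate (residue, condition) keys")
  attr(df, "experiment") <- experiment
  attr(df, "corrected") <- corrected
  class(df) <- c("rate_table", "data.frame")
  df
}

#' Fit every decay series of a collection into a rate table
#'
#' @param series_list list of [decay_series()] sharing one condition
#' @param n_mc Monte-Carlo draws per series
#' @param seed RNG seed
#' @param experiment provenance label for the resulting table
#' @return a [rate_table()]
#' @export
fit_decays <- function(series_list, n_mc = 50, seed = 1L, experiment = "") {
  fits <- lapply(seq_along(series_list), function(i)
    fit_monoexponential(series_list[[i]], n_mc = n_mc, seed = seed + i))
  rate_table(
    residue = vapply(series_list, function(s) as.character(s$residue), ""),
    rate = vapply(fits, `[[`, 1, "rate"),
    rate_err = vapply(fits, `[[`, 1, "rate_err"),
    condition = vapply(series_list, function(s) condition_key(s$condition), ""),
    experiment = experiment)
}
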