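## Detectors analysis: re-parameterize a set of relaxation rate constants
## as responses of optimized, localized sensitivity windows over
## log-correlation time z = log10(tau_c / s), instead of fitting a single
## correlation time. Rates are linear in the amplitude distribution
## theta(z): rate_i = sum_j M[i, j] * theta_j, where M[i, j] is the rate
## experiment i would show for a unit-amplitude motion at tau = 10^z_j.

#' Build the rate sensitivity matrix over a log-correlation-time grid
#'
#' Row i, column j holds the rate that a unit-amplitude motion with
#' correlation time `10^z_j` seconds would produce under condition i
#' (R1 via [r1_rate()], R1rho via [r1rho_mas()]).
#'
#' @param conditions list of [experiment_condition()] objects (>= 2), each
#'   tagged with `experiment` `"R1"` or `"R1rho"`
#' @param spin a [spin_interaction()]
#' @param z_grid grid of `log10(tau_c/s)` values
#' @return matrix `length(conditions) x length(z_grid)` with condition keys
#'   as row names; a warning is issued if two rows are identical within
#'   tolerance (degenerate design)
#' @export
build_sensitivities <- function(conditions, spin = spin_interaction(),
                                z_grid = default_z_grid()) {
  stopifnot(length(conditions) >= 2)
  M <- t(vapply(conditions, function(cond) {
    vapply(z_grid, function(z) {
      m <- motion_model(1, 10^z)
      if (cond$experiment == "R1") r1_rate(m, spin, cond)
      else r1rho_mas(m, spin, cond)
    }, numeric(1))
  }, numeric(length(z_grid))))
  rownames(M) <- vapply(conditions, condition_key, "")
  nm <- sqrt(rowSums(M^2))
  for (i in seq_len(nrow(M) - 1)) for (j in seq(i + 1, nrow(M))) {
    if (sqrt(sum((M[i, ] - M[j, ])^2)) < 1e-6 * max(nm[i], nm[j]))
      warning("degenerate conditions: rows ", i, " and ", j,
              " are identical within tolerance")
  }
  M
}

#' Default z grid: log10(tau_c/s) from -12 to -3, step 0.05
#' @return numeric vector
#' @export
default_z_grid <- function() seq(-12, -3, by = 0.05)

## Joint optimization of m localized, non-negative detector shapes within
## the span of V (n_z x m). Each shape is V %*% w_n; the objective is the
## sum of second moments about the current centers, with quadratic
## penalties enforcing non-negativity and the amplitude calibration
## sum_n shape_n(center_k) = 1 at every center (so that the response to a
## unit-amplitude motion at a center is one). Solved by BFGS with an
## analytic gradient; the problem is smooth and small (m^2 variables).
.optimize_shapes <- function(V, z, centers, lambda = 1e4, mu = 1e3) {
  m <- length(centers)
  nz <- length(z)
  mom <- vapply(centers, function(cn) (z - cn)^2, numeric(nz))
  ## scale calibration rows: indices of grid points nearest each center
  ci <- vapply(centers, function(cn) which.min(abs(z - cn)), 1L)
  obj <- function(wv) {
    W <- matrix(wv, ncol = m)
    S <- V %*% W
    tot <- rowSums(S)
    sum(mom * S) + lambda * sum(pmin(S, 0)^2) + mu * sum((tot[ci] - 1)^2)
  }
  grad <- function(wv) {
    W <- matrix(wv, ncol = m)
    S <- V %*% W
    tot <- rowSums(S)
    g_cal <- numeric(nz)
    g_cal[ci] <- 2 * mu * (tot[ci] - 1)
    G <- crossprod(V, mom + 2 * lambda * pmin(S, 0) +
                        matrix(g_cal, nz, m))
    as.numeric(G)
  }
  ## start from non-negative Gaussian bumps projected into the subspace
  W0 <- vapply(centers, function(cn) {
    g <- exp(-(z - cn)^2 / (2 * 0.35^2))
    as.numeric(crossprod(V, g / max(g)))
  }, numeric(ncol(V)))
  opt <- stats::optim(as.numeric(W0), obj, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  matrix(opt$par, ncol = m)
}

#' Optimize a set of localized detectors from a sensitivity matrix
#'
#' Detector shapes are linear combinations of the first `m` right singular
#' vectors of the sensitivity matrix, optimized to be non-negative and
#' maximally localized (minimal second moment about their centers), and
#' then jointly rescaled so that the sum of shapes approximates one inside
#' the sensitive window: with that normalization the response to a
#' unit-amplitude motion at a detector's center is close to one, so
#' responses read directly as motional amplitudes.
#'
#' @param sens sensitivity matrix from [build_sensitivities()]
#' @param m number of detectors (2 <= m <= rank of `sens`)
#' @param z_grid the z grid the matrix was built on
#' @param n_refine center-refinement iterations
#' @return an object of class `detector_set`: list with `z`, `sens`,
#'   `shapes` (n_z x m, non-negative), `basis` (the singular vectors),
#'   `centers`, `window` (logical in-window mask), `normalization`
#' @export
optimize_detectors <- function(sens, m, z_grid = default_z_grid(),
                               n_refine = 3) {
  stopifnot(ncol(sens) == length(z_grid))
  sv <- svd(sens / sqrt(rowSums(sens^2)))  # row-normalized so R1 counts
  rank <- sum(sv$d > 1e-10 * sv$d[1])
  if (m < 2 || m > rank)
    stop("m must be between 2 and the rank of the sensitivity matrix (", rank, ")")
  V <- sv$v[, seq_len(m), drop = FALSE]
  z <- z_grid
  ## subspace leverage: where the measurable part of theta(z) lives
  lev <- rowSums(V^2)
  ## initial centers: equal-mass quantiles of the leverage
  cm <- cumsum(lev); cm <- cm / cm[length(cm)]
  centers <- vapply(seq_len(m), function(n)
    z[which.min(abs(cm - (n - 0.5) / m))], numeric(1))
  W <- NULL
  for (it in seq_len(n_refine)) {
    W <- .optimize_shapes(V, z, centers)
    shapes <- V %*% W
    centers <- vapply(seq_len(m), function(n) {
      s <- pmax(shapes[, n], 0)
      sum(z * s) / sum(s)
    }, numeric(1))
    ord <- order(centers)
    centers <- centers[ord]; W <- W[, ord, drop = FALSE]
  }
  shapes <- V %*% W
  peak <- max(shapes)
  if (min(shapes) < -0.02 * peak)
    stop("non-negativity infeasible at m = ", m, "; try a smaller m")
  shapes_clipped <- pmax(shapes, 0)
  ## in-window mask: where the sum of shapes stays close to one, so a
  ## unit-amplitude motion there yields total response ~ 1
  tot <- rowSums(shapes_clipped)
  win <- abs(tot - 1) < 0.1
  structure(list(z = z, sens = sens, shapes = shapes_clipped,
                 coef = W,
                 basis = V,
                 row_scale = sqrt(rowSums(sens^2)),
                 singular_values = sv$d, m = m,
                 centers = centers, window = win,
                 normalization = "sum of shapes = 1 at detector centers"),
            class = "detector_set")
}

#' @export
print.detector_set <- function(x, ...) {
  cat(sprintf("<detector_set> %d detectors on z in [%g, %g]\n",
              x$m, min(x$z), max(x$z)))
  cat("  centers (log10 tau_c/s):", sprintf("%.2f", x$centers), "\n")
  invisible(x)
}

#' Fit detector responses for each residue
#'
#' Least-squares solution, per residue, of the measured rates in terms of
#' the detector set's singular subspace; responses are the detector-shape
#' contractions of the fitted amplitude distribution. Uncertainties by
#' Monte-Carlo resampling of the rate errors.
#'
#' @param rates a [rate_table()] covering the conditions the set was built
#'   on (rows matched by condition key); residues missing conditions get a
#'   partial fit and a flag
#' @param set a `detector_set`
#' @param n_mc Monte-Carlo draws
#' @param seed RNG seed
#' @return an object of class `detector_responses`: list with `responses`
#'   (residues x m), `errors`, `coefs` (subspace coordinates, used for
#'   back-calculation), `backcalc` (fitted rates), `flags`
#' @export
fit_responses <- function(rates, set, n_mc = 100, seed = 1L) {
  stopifnot(inherits(set, "detector_set"))
  keys <- rownames(set$sens)
  ## fixed per-experiment scaling: the same row normalization the singular
  ## basis was computed with, so the least-squares solution is exactly the
  ## subspace projection of the amplitude distribution (responses read as
  ## amplitudes); residue-specific rate errors enter through the MC draws
  P <- (set$sens / set$row_scale) %*% set$basis   # n_exp x m design
  residues <- unique(rates$residue)
  m <- set$m
  resp <- err <- matrix(NA_real_, length(residues), m,
                        dimnames = list(residues, paste0("rho", seq_len(m))))
  coefs <- matrix(NA_real_, length(residues), m, dimnames = list(residues, NULL))
  back <- matrix(NA_real_, length(residues), length(keys),
                 dimnames = list(residues, keys))
  flags <- character(length(residues)); names(flags) <- residues
  RtT <- t(set$coef)   # responses = W' x: exact shape'theta within the subspace
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (i in seq_along(residues)) {
    sub <- rates[rates$residue == residues[i], ]
    idx <- match(keys, sub$condition)
    have <- !is.na(idx)
    if (sum(have) < m) { flags[i] <- "insufficient_conditions"; next }
    if (!all(have)) flags[i] <- "partial_fit"
    y <- sub$rate[idx[have]] / set$row_scale[have]
    s <- sub$rate_err[idx[have]]
    s[!is.finite(s) | s < 0] <- 0
    s <- s / set$row_scale[have]
    A <- P[have, , drop = FALSE]
    x <- stats::coef(stats::lm.fit(A, y))
    coefs[i, ] <- x
    resp[i, ] <- as.numeric(RtT %*% x)
    back[i, have] <- as.numeric(A %*% x) * set$row_scale[have]
    draws <- vapply(seq_len(n_mc), function(k) {
      yk <- y + stats::rnorm(length(y), 0, s)
      as.numeric(RtT %*% stats::coef(stats::lm.fit(A, yk)))
    }, numeric(m))
    err[i, ] <- apply(matrix(draws, nrow = m), 1, stats::sd)
  }
  structure(list(responses = resp, errors = err, coefs = coefs,
                 backcalc = back, flags = flags),
            class = "detector_responses")
}

#' Back-calculate rates at arbitrary conditions from detector fits
#'
#' Linear reconstruction: the fitted subspace coordinates of each residue's
#' amplitude distribution are propagated through a sensitivity matrix built
#' at the requested conditions (which may differ from the design, e.g. a
#' different MAS frequency). Conditions far outside the design's
#' spin-lock/MAS range are flagged, not refused.
#'
#' @param responses a `detector_responses` from [fit_responses()]
#' @param set the `detector_set` used for the fit
#' @param conditions list of [experiment_condition()] to evaluate at
#' @param spin the [spin_interaction()] used to build the set
#' @return a [rate_table()] of back-calculated rates (rate_err = 0), with
#'   attribute `extrapolated` naming flagged conditions
#' @export
backcalc_rates <- function(responses, set, conditions,
                           spin = spin_interaction()) {
  stopifnot(inherits(responses, "detector_responses"))
  Mnew <- build_sensitivities(conditions, spin, set$z)
  Pnew <- Mnew %*% set$basis
  keys <- vapply(conditions, condition_key, "")
  pred <- responses$coefs %*% t(Pnew)
  colnames(pred) <- keys
  ok <- !is.na(responses$coefs[, 1])
  df <- rate_table(
    residue = rep(rownames(pred)[ok], times = length(keys)),
    rate = as.numeric(pred[ok, , drop = FALSE]),
    rate_err = 0,
    condition = rep(keys, each = sum(ok)),
    experiment = "backcalc")
  ## flag conditions whose spin-lock lies far outside the design range
  design_sl <- attr(set, "design_nu_sl")
  if (!is.null(design_sl) && length(design_sl)) {
    new_sl <- vapply(conditions, `[[`, 1, "nu_sl")
    attr(df, "extrapolated") <- keys[new_sl > 1.5 * max(design_sl)]
  } else attr(df, "extrapolated") <- character()
  df
}

#' Build a complete detector set from a condition design
#'
#' Convenience wrapper: builds the sensitivity matrix for the design and
#' optimizes `m` detectors, remembering the design's spin-lock strengths
#' for extrapolation checks.
#'
#' @inheritParams build_sensitivities
#' @param m number of detectors
#' @return a `detector_set`
#' @export
build_detector_set <- function(conditions, spin = spin_interaction(), m = 4,
                               z_grid = default_z_grid()) {
  sens <- build_sensitivities(conditions, spin, z_grid)
  set <- optimize_detectors(sens, m, z_grid)
  attr(set, "design_nu_sl") <- vapply(conditions, `[[`, 1, "nu_sl")
  set
}

#' Serialize a detector set to JSON
#' @param set a `detector_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_detector_set <- function(set, path) {
  obj <- list(z = set$z, sens = set$sens, shapes = set$shapes,
              basis = set$basis, m = set$m, centers = set$centers,
              window = set$window, normalization = set$normalization,
              conditions = rownames(set$sens))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a detector set from JSON written by [write_detector_set()]
#' @param path JSON file
#' @return a `detector_set`
#' @export
read_detector_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sens <- as.matrix(obj$sens); rownames(sens) <- obj$conditions
  structure(list(z = obj$z, sens = sens, shapes = as.matrix(obj$shapes),
                 basis = as.matrix(obj$basis), m = obj$m,
                 centers = obj$centers, window = obj$window,
                 normalization = obj$normalization),
            class = "detector_set")
}
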