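test_that("fast-exchange R_ex has the right limits and quench monotonicity", {
  em <- exchange_model(p_b = 0.05, k_ex = 2e4, delta_omega = 2, r2_0 = 5)
  ## omega_1 = 0 closed form
  dw_rad <- prxdyn:::ppm_to_rad(2, 14.1)
  expect_equal(rex_fast_exchange(em, 0, 14.1),
               5 + 0.95 * 0.05 * dw_rad^2 / 2e4)
  ## full quenching at very strong lock
  expect_lt(rex_fast_exchange(em, 1e9, 14.1) - 5, 1e-6)
  ## strictly decreasing in nu_1
  r <- rex_fast_exchange(em, seq(0, 5e4, by = 5e3), 14.1)
  expect_true(all(diff(r) < 0))
})

test_that("Laguerre approximation reduces to fast exchange and to r2_0", {
  ## delta_omega = 0: no exchange contribution
  em0 <- exchange_model(0.05, 1e3, 0, r1 = 0.06, r2_0 = 7)
  expect_equal(as.numeric(r1rho_laguerre(em0, 8e3, 0, 14.1)), 7)
  ## fast regime (k_ex >= 5 dw_rad): within 2% of the fast-exchange form
  em <- exchange_model(0.05, 5 * prxdyn:::ppm_to_rad(1.5, 14.1),
                       1.5, r2_0 = 5)
  for (nu in c(1e3, 3e3, 8e3, 15e3)) {
    expect_lt(abs(as.numeric(r1rho_laguerre(em, nu, 0, 14.1)) -
                    rex_fast_exchange(em, nu, 14.1)) /
                rex_fast_exchange(em, nu, 14.1), 0.02)
  }
  ## on-resonance symmetry under offset sign flip
  expect_equal(as.numeric(r1rho_laguerre(em0, 8e3, 500, 14.1)),
               as.numeric(r1rho_laguerre(em0, 8e3, -500, 14.1)))
  ## validity flag for slow exchange with large minor population
  slow <- exchange_model(0.4, 100, 5, r2_0 = 5)
  expect_false(attr(r1rho_laguerre(slow, 5e3, 0, 14.1), "approx_valid"))
})

test_that("Bloch-McConnell propagator limits and symmetries", {
  ## k_ex very large, dw = 0: population-weighted (equal) r2_0
  em <- exchange_model(0.3, 1e6, 0, r1 = 0.05, r2_0 = 8)
  expect_lt(abs(as.numeric(bm_propagator_oracle(em, 5e3, 0, 14.1,
                                                lock_time = 0.05)) - 8), 0.01)
  ## detailed balance: relabeling the states leaves the rate unchanged
  dw <- prxdyn:::ppm_to_rad(3, 14.1)
  r_ab <- prxdyn:::.bm_rate(0.9, 0.1, dw, 2e3, 0.05, 6, 5e3, 0, 0.05)
  r_ba <- prxdyn:::.bm_rate(0.1, 0.9, -dw, 2e3, 0.05, 6, 5e3, 0, 0.05)
  expect_equal(as.numeric(r_ab), as.numeric(r_ba), tolerance = 1e-6)
})

test_that("the three exchange evaluators agree in their regimes", {
  ## fast-exchange R_ex ratio (low vs high field) matches the propagator
  em <- exchange_model(0.05, 1100, 2, r1 = 0, r2_0 = 5)
  rex <- function(nu) rex_fast_exchange(em, nu, 14.1) - 5
  bm <- function(nu) as.numeric(bm_propagator_oracle(em, nu, 0, 14.1)) - 5
  expect_lt(abs(rex(2.3e3) / rex(15e3) - bm(2.3e3) / bm(15e3)) /
              (bm(2.3e3) / bm(15e3)), 0.03)
  ## Laguerre vs propagator over a (k_ex, nu_1) grid
  for (kex in c(500, 1100, 5e3, 2e4)) for (nu in c(2.3e3, 5e3, 8e3, 12e3, 15e3)) {
    emk <- exchange_model(0.05, kex, 4, r1 = 0, r2_0 = 5)
    l <- as.numeric(r1rho_laguerre(emk, nu, 0, 14.1))
    b <- as.numeric(bm_propagator_oracle(emk, nu, 0, 14.1))
    expect_lt(abs(l - b) / b, 0.05)
  }
  ## random fast-regime sweep: all three within 5%
  set.seed(21)
  for (i in 1:10) {
    dw <- runif(1, 0.5, 2)
    kex <- runif(1, 6, 20) * prxdyn:::ppm_to_rad(dw, 14.1)
    emr <- exchange_model(runif(1, 0.02, 0.3), kex, dw, r2_0 = 5)
    nu <- runif(1, 1e3, 15e3)
    v <- c(rex_fast_exchange(emr, nu, 14.1),
           as.numeric(r1rho_laguerre(emr, nu, 0, 14.1)),
           as.numeric(bm_propagator_oracle(emr, nu, 0, 14.1)))
    expect_lt((max(v) - min(v)) / min(v), 0.05)
  }
})

test_that("joint dispersion fit recovers parameters from clean curves", {
  nu <- c(2.3, 3.2, 4.5, 6.3, 8, 10, 15) * 1e3
  mk_curve <- function(res, dw, kex = 1100) {
    em <- exchange_model(0.05, kex, dw, r1 = 0, r2_0 = 5)
    dispersion_curve(res, nu, as.numeric(r1rho_laguerre(em, nu, 0, 14.1)),
                     rep(0.3, length(nu)), corrected = TRUE)
  }
  curves <- lapply(1:5, function(i) mk_curve(i, 7 + i * 0.5))
  fit <- fit_dispersion_joint(curves, b0 = 14.1)
  ## noiseless identifiability: the optimizer finds the generating k_ex
  expect_lt(abs(fit$k_ex - 1100) / 1100, 0.02)
  expect_equal(fit$per_residue$delta_omega, 7 + (1:5) * 0.5, tolerance = 0.02)
  ## zero-dispersion curves give delta_omega consistent with 0
  flat <- lapply(1:3, function(i)
    dispersion_curve(i, nu, rep(5, length(nu)), rep(0.3, length(nu))))
  f0 <- fit_dispersion_joint(flat, b0 = 14.1)
  err0 <- f0$per_residue$delta_omega_err
  err0[!is.finite(err0)] <- 0
  expect_true(all(abs(f0$per_residue$delta_omega) < pmax(2 * err0, 0.5)))
  ## a single curve in the joint fit is a (degenerate) perfect fit of it:
  ## the curve is reproduced even though (k_ex, delta_omega) trade off
  f1 <- fit_dispersion_joint(curves[[1]], b0 = 14.1)
  em1 <- exchange_model(0.05, f1$k_ex, f1$per_residue$delta_omega[1],
                        r2_0 = max(f1$per_residue$r2_0[1], 0))
  pred <- as.numeric(r1rho_laguerre(em1, nu, 0, 14.1)) +
    min(f1$per_residue$r2_0[1], 0)
  expect_lt(max(abs(pred - curves[[1]]$rates) / curves[[1]]$rates), 1e-3)
  expect_error(fit_dispersion_joint(list(dispersion_curve(1, nu[1:3],
                                                          rep(5, 3)))),
               ">= 4")
})
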