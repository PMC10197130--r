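test_that("spectral density matches closed forms", {
  m <- motion_model(1, 1e-9)
  expect_equal(spectral_density(m, 0), 0.4 * 1e-9)
  ## Lorentzian half-point at omega*tau = 1
  expect_equal(spectral_density(m, 1e9), 0.5 * spectral_density(m, 0))
  ## fully rigid site
  rigid <- motion_model()
  expect_equal(spectral_density(rigid, c(0, 1e8, 1e9)), c(0, 0, 0))
  ## invalid models are refused
  expect_error(motion_model(-0.1, 1e-9), "amplitude")
  expect_error(motion_model(0.1, -1e-9), "tau")
  expect_error(motion_model(c(0.6, 0.6), c(1e-9, 1e-8)), "sum")
})

test_that("J(omega) is non-negative and non-increasing for random models", {
  set.seed(11)
  omega <- 10^seq(4, 10, length.out = 40)
  for (i in 1:25) {
    k <- sample(1:3, 1)
    a <- runif(k, 0, 0.3)
    m <- motion_model(a / max(1, sum(a) / 0.9), 10^runif(k, -11, -4),
                      overall_tau = if (i %% 2) 10^runif(1, -9, -7.5))
    J <- spectral_density(m, omega)
    expect_true(all(J >= 0))
    expect_true(all(diff(J) <= 1e-15))
  }
})

test_that("solution spectral density combines overall and internal times", {
  ## pure overall tumbling: S^2 = 1
  m <- motion_model(overall_tau = 5e-9)
  expect_equal(spectral_density(m, 0), 0.4 * 5e-9)
  ## internal time combines harmonically
  m2 <- motion_model(1, 1e-9, overall_tau = 5e-9)
  tau_eff <- 1 / (1 / 5e-9 + 1 / 1e-9)
  expect_equal(spectral_density(m2, 0), 0.4 * tau_eff)
})

test_that("R1 is zero for rigid sites, linear in amplitude, peaks near 1/omega_N", {
  cond <- experiment_condition(nu_mas = 55e3, experiment = "R1")
  expect_equal(r1_rate(motion_model(), spin_std, cond), 0)
  r1a <- r1_rate(motion_model(0.05, 1e-9), spin_std, cond)
  r1b <- r1_rate(motion_model(0.10, 1e-9), spin_std, cond)
  expect_equal(r1b, 2 * r1a)
  ## grid search over tau reproduces the single-maximum shape
  taus <- 10^seq(-11, -6, by = 0.05)
  r1 <- vapply(taus, function(tau)
    r1_rate(motion_model(0.1, tau), spin_std, cond), numeric(1))
  peak_tau <- taus[which.max(r1)]
  expect_lt(abs(log10(peak_tau) - log10(1 / (abs(-2.7126180436e7) * 14.1))), 0.35)
  ## single interior maximum
  sgn <- sign(diff(r1))
  expect_equal(sum(diff(sgn) != 0), 1)
})

test_that("MAS R1rho: rigid zero, NERRD monotonicity, flatness for fast motion", {
  cond <- function(nu) experiment_condition(nu_mas = 45e3, nu_sl = nu)
  expect_equal(r1rho_mas(motion_model(), spin_std, cond(10e3)), 0)
  ## non-flat, monotonically rising profile for a 10 us motion
  slow <- motion_model(0.05, 1e-5)
  nus <- seq(10e3, 41e3, by = 1e3)
  prof <- vapply(nus, function(nu) r1rho_mas(slow, spin_std, cond(nu)),
                 numeric(1))
  expect_true(all(diff(prof) > 0))
  ## flat profiles (spread < 1% of mean) for every tau < 100 ns
  for (tau in c(1e-9, 1e-8, 5e-8, 9e-8)) {
    fast <- motion_model(0.05, tau)
    p <- vapply(seq(2e3, 0.8 * 45e3, length.out = 10), function(nu)
      r1rho_mas(fast, spin_std, cond(nu)), numeric(1))
    expect_lt((max(p) - min(p)) / mean(p), 0.01)
  }
  ## superposition: linear in each component amplitude
  m1 <- motion_model(0.03, 1e-5); m2 <- motion_model(0.02, 5e-8)
  msum <- motion_model(c(0.03, 0.02), c(1e-5, 5e-8))
  expect_equal(r1rho_mas(msum, spin_std, cond(20e3)),
               r1rho_mas(m1, spin_std, cond(20e3)) +
                 r1rho_mas(m2, spin_std, cond(20e3)))
  ## solution-state condition is routed elsewhere
  expect_error(r1rho_mas(slow, spin_std, experiment_condition(nu_mas = 0)),
               "solution")
})

test_that("offset correction follows the tilted-frame geometry", {
  expect_equal(r1rho_offset_correct(6, 0.06, offset = 0, nu_sl = 10e3), 6)
  ## R1rho_obs = R1 is a fixed point at any geometry
  expect_equal(r1rho_offset_correct(0.06, 0.06, offset = 3e3, nu_sl = 5e3),
               0.06)
  ## 45-degree tilt arithmetic
  expect_equal(r1rho_offset_correct(6, 0.06, offset = 5e3, nu_sl = 5e3),
               (6 - 0.06 * 0.5) / 0.5)
  expect_error(r1rho_offset_correct(6, 0.06, offset = 1e6, nu_sl = 10),
               "unstable")
})

test_that("TRACT tau_c inverts the cross-correlated rate map", {
  ## forward-then-invert roundtrip at the dimer's 27 ns
  eta <- eta_xy(27e-9, spin_std)
  tau <- tract_tauc(r_alpha = 10, r_beta = 10 + 2 * eta, spin_std)
  expect_lt(abs(tau - 27e-9) / 27e-9, 1e-3)
  ## slow-tumbling regime: doubling the rate difference ~ doubles tau_c
  tau2 <- tract_tauc(10, 10 + 4 * eta, spin_std)
  expect_lt(abs(tau2 - 2 * tau) / (2 * tau), 0.02)
  ## vanishing difference returns a vanishing tau_c
  expect_lt(tract_tauc(10, 10 + 1e-6, spin_std), 1e-11)
  expect_error(tract_tauc(10, 9, spin_std), "exceed")
})
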