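test_that("sensitivity matrix rows peak where the physics says", {
  z <- default_z_grid()
  sens <- build_sensitivities(design_nerrd_r1, spin_std, z)
  expect_true(all(sens >= 0))
  ## R1 row peaks near z = log10(1/omega_N)
  r1_row <- sens[nrow(sens), ]
  z_peak <- z[which.max(r1_row)]
  expect_lt(abs(z_peak - log10(1 / (abs(-2.7126180436e7) * 14.1))), 0.3)
  ## the near-rotary R1rho row (nu_1 = 41 kHz at 45 kHz MAS) is largest at
  ## slow correlation times
  nr_row <- sens[7, ]
  expect_gte(z[which.max(nr_row)], -6)
  ## degenerate designs warn
  expect_warning(build_sensitivities(list(designs_std$nerrd[[1]],
                                          designs_std$nerrd[[1]]),
                                     spin_std, z), "degenerate")
})

test_that("optimized detectors are non-negative, ordered and localized", {
  set4 <- build_detector_set(design_nerrd_r1, spin_std, m = 4)
  expect_true(all(set4$shapes >= 0))
  expect_true(all(diff(set4$centers) > 0))
  ## sum of shapes is one at the centers (amplitude calibration)
  tot <- rowSums(set4$shapes)
  at_centers <- tot[vapply(set4$centers, function(cn)
    which.min(abs(set4$z - cn)), 1L)]
  expect_true(all(abs(at_centers - 1) < 0.05))
  ## requesting more detectors than the design rank fails
  expect_error(optimize_detectors(set4$sens, m = 9), "rank")
})

test_that("responses recover single-tau amplitudes inside detector windows", {
  set4 <- build_detector_set(design_nerrd_r1, spin_std, m = 4)
  for (zc in set4$centers) {
    resp <- fit_responses(rates_for(motion_model(0.1, 10^zc),
                                    design_nerrd_r1), set4, n_mc = 5)
    expect_lt(abs(sum(resp$responses) - 0.1) / 0.1, 0.1)
    ## response mass concentrates in the window containing the motion
    expect_equal(which.max(resp$responses),
                 which.min(abs(set4$centers - zc)))
  }
  ## documented degradation outside the windows (design blind spot ~ 100 ns)
  resp_out <- fit_responses(rates_for(motion_model(0.1, 1e-7),
                                      design_nerrd_r1), set4, n_mc = 5)
  expect_lt(sum(resp_out$responses), 0.05)
})

test_that("responses are linear and vanish for zero rates", {
  set4 <- build_detector_set(design_nerrd_r1, spin_std, m = 4)
  zero <- rates_for(motion_model(), design_nerrd_r1)
  expect_true(all(abs(fit_responses(zero, set4, n_mc = 2)$responses) < 1e-12))
  ra <- rates_for(motion_model(0.05, 1e-5), design_nerrd_r1)
  rb <- rates_for(motion_model(0.03, 3e-9), design_nerrd_r1)
  rsum <- rate_table(ra$residue, ra$rate + rb$rate, ra$rate_err, ra$condition)
  expect_equal(
    as.numeric(fit_responses(rsum, set4, n_mc = 2)$responses),
    as.numeric(fit_responses(ra, set4, n_mc = 2)$responses +
                 fit_responses(rb, set4, n_mc = 2)$responses),
    tolerance = 1e-8)
})

test_that("three and four detectors give similar single-tau responses", {
  set3 <- build_detector_set(design_nerrd_r1, spin_std, m = 3)
  set4 <- build_detector_set(design_nerrd_r1, spin_std, m = 4)
  ## compare at positions inside both window sets
  for (zc in c(-8.7, -5.2, -4.5)) {
    rt <- rates_for(motion_model(0.1, 10^zc), design_nerrd_r1)
    t3 <- sum(fit_responses(rt, set3, n_mc = 2)$responses)
    t4 <- sum(fit_responses(rt, set4, n_mc = 2)$responses)
    expect_lt(abs(t3 - t4) / 0.1, 0.10)
  }
})

test_that("back-calculation reconstructs rates and round-trips", {
  set4 <- build_detector_set(design_nerrd_r1, spin_std, m = 4)
  rt <- rates_for(motion_model(0.05, 8e-6), design_nerrd_r1)
  resp <- fit_responses(rt, set4, n_mc = 2)
  ## projection identity at the design conditions
  bc <- backcalc_rates(resp, set4, design_nerrd_r1, spin_std)
  expect_equal(bc$rate[match(rt$condition, bc$condition)],
               as.numeric(resp$backcalc["X", rt$condition]))
  ## round-trip within 5% at design conditions
  expect_lt(max(abs(bc$rate[match(rt$condition, bc$condition)] - rt$rate) /
                  pmax(rt$rate, 0.01)), 0.05)
  ## zero responses give zero rates
  resp0 <- fit_responses(rates_for(motion_model(), design_nerrd_r1),
                         set4, n_mc = 2)
  bc0 <- backcalc_rates(resp0, set4, designs_std$bmrd, spin_std)
  expect_true(all(abs(bc0$rate) < 1e-12))
})

test_that("detector sets serialize to JSON and back", {
  set3 <- build_detector_set(design_nerrd_r1, spin_std, m = 3)
  p <- tempfile(fileext = ".json")
  write_detector_set(set3, p)
  back <- read_detector_set(p)
  expect_equal(back$z, set3$z)
  expect_equal(unname(back$shapes), unname(set3$shapes), tolerance = 1e-12)
  expect_equal(back$centers, set3$centers)
  unlink(p)
})
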