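## Pipeline tests run on reduced-size inputs where possible; the full
## oxidized run (196 residues x 15 conditions) is exercised once.

test_that("correct_bmrd cancels exactly when data equal the back-calculation", {
  set4 <- build_detector_set(design_nerrd_r1, spin_std, m = 4)
  rt <- rates_for(motion_model(0.03, 8e-6), design_nerrd_r1, err = 0.1)
  resp <- fit_responses(rt, set4, n_mc = 2)
  bc <- backcalc_rates(resp, set4, designs_std$bmrd, spin_std)
  bmrd <- rate_table(bc$residue, bc$rate, rep(0.1, nrow(bc)), bc$condition)
  rep5 <- correct_bmrd(bmrd, resp, set4, designs_std$bmrd, spin_std,
                       plateau = 5)
  expect_equal(rep5$corrected, rep(5, nrow(rep5)))
  ## plateau = 0 leaves exchange-free residues close to zero
  rep0 <- correct_bmrd(bmrd, resp, set4, designs_std$bmrd, spin_std,
                       plateau = 0)
  expect_true(all(abs(rep0$corrected) < 1e-9))
  ## a second application is refused
  cor_rt <- rate_table(rep5$residue, rep5$corrected, rep5$rate_err,
                       rep5$condition, corrected = TRUE)
  expect_error(correct_bmrd(cor_rt, resp, set4, designs_std$bmrd, spin_std),
               "already")
  ## missing NERRD coverage is flagged, not dropped
  bmrd2 <- rate_table(c(bmrd$residue, rep("Y", 2)),
                      c(bmrd$rate, 5, 5), rep(0.1, nrow(bmrd) + 2),
                      c(bmrd$condition,
                        vapply(designs_std$bmrd[1:2], condition_key, "")))
  rep2 <- correct_bmrd(bmrd2, resp, set4, designs_std$bmrd, spin_std)
  expect_true(all(grepl("no_nerrd_coverage",
                        rep2$flag[rep2$residue == "Y"])))
})

test_that("a residue with both us motion and exchange corrects to pure exchange", {
  ## separable truth: dipolar/CSA part from the motion model (fast
  ## libration plus a global-level microsecond component, as the
  ## generator's exchange-cluster residues carry), exchange part from the
  ## Laguerre model; noise-free emission
  m <- motion_model(c(0.02, 0.01), c(3e-9, 1e-5))
  em <- exchange_model(0.05, 1100, 9, r2_0 = 0)
  set6 <- build_detector_set(design_nerrd_r1, spin_std, m = 6)
  rt_n <- rates_for(m, design_nerrd_r1, err = 0.1)
  resp <- fit_responses(rt_n, set6, n_mc = 2)
  sls <- vapply(designs_std$bmrd, `[[`, 1, "nu_sl")
  rex <- as.numeric(r1rho_laguerre(em, sls, 0, 14.1))
  r_dip <- vapply(designs_std$bmrd, function(cn)
    r1rho_mas(m, spin_std, cn), numeric(1))
  bmrd <- rate_table(rep("X", 7), r_dip + rex, rep(0.1, 7),
                     vapply(designs_std$bmrd, condition_key, ""))
  rep5 <- correct_bmrd(bmrd, resp, set6, designs_std$bmrd, spin_std,
                       plateau = 5)
  rep5 <- rep5[match(bmrd$condition, rep5$condition), ]
  ## corrected curve matches the pure-exchange truth within 10% at >= 4 kHz
  keep <- sls >= 4e3
  expect_lt(max(abs(rep5$corrected[keep] - (rex[keep] + 5)) /
                  (rex[keep] + 5)), 0.10)
})

test_that("the full oxidized pipeline flags the right residues deterministically", {
  cfg <- default_pipeline_config(seed = 7)
  cfg$n_mc <- 20
  truth <- make_scenario("oxidized", seed = 7)
  dec <- list(r1 = emit_decays(truth, cfg$designs$r1, spin_std, seed = 8),
              nerrd = emit_decays(truth, cfg$designs$nerrd, spin_std, seed = 9),
              bmrd = emit_decays(truth, cfg$designs$bmrd, spin_std, seed = 10))
  res <- suppressMessages(run_pipeline(dec, cfg, spin_std))
  ## exchange-type flags are a subset of the generator's exchange cluster
  expect_true(all(res$significance$flagged %in%
                    as.character(truth$exchange_residues)))
  expect_gte(length(res$significance$flagged), 2)
  ## nearly all residues show non-flat NERRD profiles in the oxidized state
  expect_gte(length(res$nerrd_significance$flagged), 0.9 * 196)
  ## determinism: identical artifacts from identical config and seed
  out1 <- tempfile(); out2 <- tempfile()
  write_pipeline_artifacts(res, out1)
  res_b <- suppressMessages(run_pipeline(dec, cfg, spin_std))
  write_pipeline_artifacts(res_b, out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("rigid and patch-only scenarios flag as designed", {
  cfg <- default_pipeline_config(seed = 11)
  cfg$n_mc <- 30
  ## rigid dataset: no true dispersion of either kind; with 196 residues
  ## and Gaussian noise the one-sided 3x-SD rule admits at most an
  ## occasional single false positive
  red <- make_scenario("reduced", seed = 11)
  dec <- list(r1 = emit_decays(red, cfg$designs$r1, spin_std, seed = 12),
              nerrd = emit_decays(red, cfg$designs$nerrd, spin_std, seed = 13),
              bmrd = emit_decays(red, cfg$designs$bmrd, spin_std, seed = 14))
  res <- suppressMessages(run_pipeline(dec, cfg, spin_std))
  expect_lte(length(res$significance$flagged), 1)
  expect_lte(length(res$nerrd_significance$flagged), 2)
  ## us-patch dataset: the NERRD flatness test flags >= 90% of the patch
  po <- make_scenario("custom", seed = 11,
                      custom = list(ox_a_us = 0,
                                    exchange_residues = integer()))
  dec_po <- list(r1 = emit_decays(po, cfg$designs$r1, spin_std, seed = 15),
                 nerrd = emit_decays(po, cfg$designs$nerrd, spin_std, seed = 16),
                 bmrd = emit_decays(po, cfg$designs$bmrd, spin_std, seed = 17))
  res_po <- suppressMessages(run_pipeline(dec_po, cfg, spin_std))
  expect_gte(mean(as.character(po$patch) %in%
                    res_po$nerrd_significance$flagged), 0.9)
})
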