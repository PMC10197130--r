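test_that("molecular mass matches the standard residue-mass table", {
  g <- sequence_record("gly", "G")
  expect_equal(molecular_mass(g), 0.07507, tolerance = 1e-4)
  ## multiplicity is linear
  s <- sequence_record("s", "ACDEFGHIKLMNPQRSTVWY")
  expect_equal(molecular_mass(s, 10), 10 * molecular_mass(s, 1))
  ## strict additivity over concatenation (minus one water per join)
  s1 <- sequence_record("a", "ACDEF"); s2 <- sequence_record("b", "GHIKL")
  s12 <- sequence_record("ab", "ACDEFGHIKL")
  expect_equal(molecular_mass(s12),
               molecular_mass(s1) + molecular_mass(s2) - 18.01528 / 1000)
  ## independent cross-check of the mass table on a known tripeptide:
  ## AGS = 71.0788 + 57.0519 + 87.0782 + 18.0153 = 233.224 Da
  expect_equal(molecular_mass(sequence_record("x", "AGS")), 0.233224,
               tolerance = 1e-5)
  expect_error(sequence_record("bad", "ACDEFZ"), "unknown residue")
})

test_that("extinction coefficients follow the Pace convention", {
  expect_equal(extinction_coefficient(sequence_record("x", "AGSDE")), 0)
  expect_equal(extinction_coefficient(sequence_record("x", "WWY")), 12490)
  cc <- sequence_record("x", "CCWC")
  expect_equal(extinction_coefficient(cc, cystines = 1), 5500 + 125)
  expect_error(extinction_coefficient(cc, cystines = 2), "cystines")
  ## additive over concatenated sequences
  e1 <- extinction_coefficient(sequence_record("a", "WYA"))
  e2 <- extinction_coefficient(sequence_record("b", "YYG"))
  expect_equal(extinction_coefficient(sequence_record("ab", "WYAYYG")),
               e1 + e2)
})

test_that("expected amide counts follow the stated conventions", {
  expect_equal(expected_amides(sequence_record("p", "PPPP")), 0)
  expect_equal(expected_amides(sequence_record("x", "APA")), 2)
  expect_equal(expected_amides(sequence_record("x", "APA"), "exclude-first"), 1)
})

test_that("the synthetic stand-in reproduces the published aggregate values", {
  rec <- tsa1_standin()
  expect_equal(nchar(rec$seq), 196)
  expect_equal(expected_amides(rec), 184)
  expect_equal(as.numeric(extinction_coefficient(rec, cystines = 1)), 24535)
  expect_equal(molecular_mass(rec, 10), 216, tolerance = 0.005)
  expect_equal(rec$residues[c(47, 170)], c("C", "C"))
})

test_that("inter-residue distances resolve atoms and gamma conventions", {
  s <- toy_structure()
  a <- list(chain = "A", resno = 3, atom = "CA")
  expect_equal(inter_residue_distance(s, a, a), 0)
  ## unit offset between matched N atoms of the two identical chains... use CA/N
  b <- list(chain = "A", resno = 3, atom = "N")
  d <- inter_residue_distance(s, a, b)
  expect_equal(d, sqrt(1 + 0.2^2 + 0.3^2))
  expect_error(inter_residue_distance(s, a, list(chain = "A", resno = 3,
                                                 atom = "ZZ")), "not found")
  expect_error(inter_residue_distance(s, a, list(chain = "Q", resno = 3,
                                                 atom = "CA")), "no atoms")
  ## the stand-in decamer carries the designed peroxidatic-site distance
  dec <- synthetic_decamer_structure(cp_cr_distance = 13)
  d47 <- inter_residue_distance(dec, list(chain = "A", resno = 47,
                                          atom = "gamma"),
                                list(chain = "B", resno = 170, atom = "SG"))
  expect_equal(d47, 13, tolerance = 1e-6)
})

test_that("B-factor profiles average backbone atoms and track gradients", {
  s <- toy_structure()
  bp <- bfactor_profile(s)
  expect_true(all(bp$summary$b_mean == 20))
  expect_true(all(bp$summary$b_max - bp$summary$b_min == 0))
  ## the stand-in decamer rises toward the C terminus, low peroxidatic helix
  dec <- synthetic_decamer_structure()
  bp2 <- bfactor_profile(dec)$summary
  expect_gt(bp2$b_mean[bp2$resno == 196], bp2$b_mean[bp2$resno == 100])
  expect_lt(mean(bp2$b_mean[bp2$resno %in% 38:55]),
            mean(bp2$b_mean[bp2$resno %in% 100:120]))
  expect_true(all(diff(bp2$b_mean[bp2$resno >= 170]) >= 0))
})

test_that("pairwise superposition RMSD behaves like Kabsch should", {
  s <- toy_structure()
  r <- superpose_rmsd(s)
  expect_equal(unname(diag(r)), c(0, 0))
  expect_true(isSymmetric(r))
  ## identical chains superpose to zero
  expect_lt(r["A", "B"], 0.01)
  ## invariance under a random rigid-body transform of one chain
  for (sd in 1:3) {
    r2 <- superpose_rmsd(rotate_chain(s, "B", seed = sd))
    expect_lt(r2["A", "B"], 0.01)
  }
  ## a single displaced atom gives RMSD ~ d/sqrt(N) (closed form; the
  ## optimal refit reduces it by O(1/N))
  s3 <- toy_structure()
  at <- s3$atoms
  sel <- which(at$chain == "B" & at$resno == 5 & at$elety == "CA")
  at$x[sel] <- at$x[sel] + 2
  r3 <- superpose_rmsd(structure_model(at))
  expect_equal(r3["A", "B"], 2 / sqrt(12 * 4), tolerance = 0.05)
})

test_that("subunit heterogeneity shows up in the decamer RMSD matrix", {
  dec <- synthetic_decamer_structure(heterogeneity = 0.6, seed = 2)
  r <- superpose_rmsd(dec, chains = c("A", "C", "E"))
  off <- r[upper.tri(r)]
  expect_true(all(off > 0.3))
  dec0 <- synthetic_decamer_structure(heterogeneity = 0)
  r0 <- superpose_rmsd(dec0, chains = c("A", "C", "E"))
  expect_true(all(r0[upper.tri(r0)] < 0.01))
})
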