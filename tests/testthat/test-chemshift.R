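rc <- random_coil_fixture()

test_that("secondary shifts vanish at the reference and detect helix offsets", {
  idx <- match(c("A", "L", "K", "E"), rc$restype)
  shifts <- data.frame(residue = 1:4, restype = rc$restype[idx],
                       ca = rc$ca[idx], cb = rc$cb[idx])
  out <- secondary_shift(shifts, rc)
  expect_equal(out$delta, rep(0, 4))
  ## +3/-1 helix offsets give ~ +4 ppm
  shifts2 <- shifts
  shifts2$ca <- shifts2$ca + 3
  shifts2$cb <- shifts2$cb - 1
  expect_equal(secondary_shift(shifts2, rc)$delta, rep(4, 4))
  ## glycine is scored on CA only and flagged
  g <- data.frame(residue = 9, restype = "G", ca = rc$ca[rc$restype == "G"] + 2,
                  cb = NA)
  outg <- secondary_shift(g, rc)
  expect_equal(outg$flag, "ca_only")
  expect_equal(outg$delta, 2)
  ## missing reference names the residue
  bad <- data.frame(residue = 42, restype = "X1", ca = 50, cb = 30)
  expect_error(secondary_shift(bad, rc), "42")
})

test_that("antisymmetry and referencing invariance of secondary shifts", {
  idx <- match(c("A", "L", "V"), rc$restype)
  obs <- data.frame(residue = 1:3, restype = rc$restype[idx],
                    ca = rc$ca[idx] + c(1, -2, 0.5),
                    cb = rc$cb[idx] + c(-0.5, 1, 0))
  d1 <- secondary_shift(obs, rc)$delta
  ## swapping observed and reference negates the secondary shift
  rc_as_obs <- data.frame(residue = 1:3, restype = obs$restype,
                          ca = rc$ca[idx], cb = rc$cb[idx])
  obs_as_ref <- data.frame(restype = obs$restype, ca = obs$ca, cb = obs$cb)
  d2 <- secondary_shift(rc_as_obs, obs_as_ref)$delta
  expect_equal(d2, -d1)
  ## a uniform referencing offset applied to both tables cancels
  rc_off <- utils::read.csv(system.file("extdata",
                                        "random_coil_ca_cb_offset.csv",
                                        package = "prxdyn"))
  obs_off <- obs
  obs_off$ca <- obs_off$ca + 0.12
  obs_off$cb <- obs_off$cb + 0.12
  expect_equal(secondary_shift(obs_off, rc_off)$delta, d1)
})

test_that("secondary-structure classification thresholds and runs", {
  expect_equal(nrow(classify_sse(1:20, rep(0, 20))), 0)
  seg <- classify_sse(1:10, c(0, rep(2, 6), 0, 0, 0))
  expect_equal(seg$type, "helix")
  expect_equal(c(seg$start, seg$end), c(2, 7))
  ## runs shorter than min_run are coil
  expect_equal(nrow(classify_sse(1:10, c(rep(2, 3), rep(0, 7)))), 0)
  ## sequence gaps break runs
  seg2 <- classify_sse(c(1:3, 10:12), rep(-2, 6))
  expect_equal(nrow(seg2), 0)
  expect_error(classify_sse(1:5, rep(0, 5), min_run = 2), "min_run")
})

test_that("generator shift tables classify as designed, marginal helix as coil", {
  em <- emit_shift_table(rc, seed = 3)
  sec <- secondary_shift(em$shifts, rc)
  segs <- classify_sse(sec$residue, sec$delta)
  helix_res <- unlist(lapply(which(segs$type == "helix"), function(i)
    segs$start[i]:segs$end[i]))
  strand_res <- unlist(lapply(which(segs$type == "strand"), function(i)
    segs$start[i]:segs$end[i]))
  expect_true(all(15:25 %in% helix_res))
  expect_true(all(60:66 %in% strand_res))
  ## the marginally stable helix (~ +0.5 ppm) stays coil
  expect_false(any(38:48 %in% helix_res))
  ## helix segment shows ~ +4 ppm secondary shifts
  expect_equal(mean(sec$delta[15:25]), 4, tolerance = 0.1)
})

test_that("the NMR-STAR shift-loop reader parses a minimal file", {
  star <- c("data_test", "", "save_shifts", "loop_",
            "  _Atom_chem_shift.ID", "  _Atom_chem_shift.Seq_ID",
            "  _Atom_chem_shift.Comp_ID", "  _Atom_chem_shift.Atom_ID",
            "  _Atom_chem_shift.Val",
            "  1 5 ALA CA 52.9", "  2 5 ALA CB 18.7", "  3 6 GLY CA 45.4",
            "stop_", "save_")
  p <- tempfile(fileext = ".str")
  writeLines(star, p)
  df <- read_star_shifts(p)
  expect_equal(nrow(df), 3)
  expect_equal(df$restype, c("A", "A", "G"))
  wide <- shifts_to_wide(df)
  expect_equal(wide$ca, c(52.9, 45.4))
  expect_equal(wide$cb, c(18.7, NA))
  writeLines(c("data_x", "loop_", "_Other.tag", "1", "stop_"), p)
  expect_error(read_star_shifts(p), "Atom_chem_shift")
  unlink(p)
})
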