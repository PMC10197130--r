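## Synthetic-data generator: produces every input table the pipeline
## consumes, with known per-residue ground truth that mimics the biology of
## a 2-Cys peroxiredoxin decamer: a rigid reduced-state core with ns-mobile
## loops, an oxidized state with microsecond motion across the protein and
## a high-amplitude patch around the peroxidatic helix, a five-residue
## exchange cluster at the dimer-dimer interface, disordered C-terminal
## methyls in the dimer, and a temperature-driven decamer-dimer transition.
##
## The generator's defaults are calibrated once so that the emitted
## reduced/oxidized cohorts reproduce the reference cohort statistics
## (reduced R1rho ~ 3.9 s^-1 mean / 2.9 s^-1 median at 10 kHz spin-lock and
## R1 ~ 0.057 s^-1; oxidized R1rho ~ 9.6 s^-1, i.e. ~2.5-3x the reduced
## mean); see the methods vignette for the calibration.

N_RESIDUES <- 196

## Frozen scenario constants (see vignette for provenance)
.scn <- list(
  a_fast = 0.015,   tau_fast = 3e-9,    # ps-ns libration component
  a_slow = 0.033,   tau_slow = 5.5e-8,  # tens-of-ns component (sets R1rho floor)
  loop_residues = c(30, 31, 117, 167),  # ns-mobile loops (K30/G31-like)
  loop_boost = 2.5,
  cterm_from = 141, cterm_boost = 2.6,  # mobile tail: residues 141..C-term
  ox_a_us = 0.0026, ox_tau_us = 1e-5,   # global us component of the oxidized state
  patch = 38:55,                        # peroxidatic-helix NERRD patch
  patch_a_us = c(0.03, 0.1), patch_tau_us = c(5e-6, 5e-5),
  exchange_residues = c(74, 76, 78, 80, 82),   # dimer-dimer interface cluster
  kex = 1100, p_b = 0.05, dw_range = c(8, 11), # two-state exchange truth
  tail_methyls_from = 167,              # disordered C-terminal methyls
  s2_tail = 0.1, s2_core = c(0.6, 0.9),
  tau_c_dimer = 27e-9,                  # overall tumbling of the dimer (D2O)
  t_mid = 315, dh_vant_hoff = 1.5e5,    # decamer-dimer transition truth
  d_decamer = 4.5e-11, d_dimer = 7.7e-11)  # m^2/s at 298 K

#' Default noise configuration of the generator
#'
#' `rate`: SD added to rate constants (s^-1); `intensity`: relative SD on
#' decay intensities; `tq`: relative SD on 3Q/SQ ratios; `dosy`: relative
#' SD on DOSY intensities; `shift`: SD on chemical shifts (ppm).
#' @return named list
#' @export
default_noise <- function() {
  list(rate = 0.3, intensity = 0.02, tq = 0.05, dosy = 0.03, shift = 0.05)
}

#' Default experimental designs mirroring the reference study
#'
#' NERRD: seven R1rho spin-lock strengths 10-41 kHz at 45 kHz MAS; BMRD:
#' seven spin-lock strengths 2.3-15 kHz at 55 kHz MAS; R1 at 55 kHz MAS;
#' all at 14.1 T. The 10 kHz BMRD point doubles as the cohort-statistics
#' reference condition.
#'
#' @param b0 static field in tesla
#' @return list of condition lists: `nerrd`, `bmrd`, `r1`
#' @export
default_designs <- function(b0 = 14.1) {
  nerrd_sl <- c(10, 15, 20, 25, 30, 35, 41) * 1e3
  bmrd_sl <- c(2.3, 3.2, 4.5, 6.3, 8, 10, 15) * 1e3
  list(
    nerrd = lapply(nerrd_sl, function(nu)
      experiment_condition(b0 = b0, nu_mas = 45e3, nu_sl = nu,
                           experiment = "R1rho")),
    bmrd = lapply(bmrd_sl, function(nu)
      experiment_condition(b0 = b0, nu_mas = 55e3, nu_sl = nu,
                           experiment = "R1rho")),
    r1 = list(experiment_condition(b0 = b0, nu_mas = 55e3,
                                   experiment = "R1")))
}

#' Generate a ground-truth dynamics scenario
#'
#' `"reduced"`: small-amplitude ns motion everywhere, enhanced in loop
#' residues and the C-terminal stretch; flat NERRD profiles. `"oxidized"`:
#' additionally a global microsecond component, a contiguous
#' high-amplitude microsecond patch around the peroxidatic helix
#' (non-flat NERRD), and a five-residue exchange cluster at the
#' dimer-dimer interface (k_ex = 1100 s^-1). `"dimer"`: methyl order
#' parameter profile with a disordered C-terminal tail (S^2 ~ 0.1), the
#' 27 ns overall tumbling time, and the decamer-dimer transition truth.
#'
#' @param name `"reduced"`, `"oxidized"`, `"dimer"` or `"custom"` (an
#'   oxidized-type scenario whose constants are overridden by `custom`)
#' @param seed RNG seed; the same (name, seed) always returns the same truth
#' @param noise noise configuration, see [default_noise()]
#' @param custom named list overriding scenario constants for
#'   `name = "custom"` (e.g. `list(ox_a_us = 0)` for a patch-only dataset,
#'   or `list(exchange_residues = integer())` to disable exchange)
#' @return an object of class `synthetic_truth`
#' @export
make_scenario <- function(name = c("reduced", "oxidized", "dimer", "custom"),
                          seed = 1L, noise = default_noise(),
                          custom = list()) {
  name <- match.arg(name)
  scn <- .scn
  if (name == "custom") {
    unknown <- setdiff(names(custom), names(scn))
    if (length(unknown))
      stop("unknown scenario constant(s): ", paste(unknown, collapse = ", "))
    scn <- utils::modifyList(scn, custom)
  } else if (length(custom)) {
    stop("custom overrides are only allowed with name = \"custom\"")
  }
  oxidized_like <- name %in% c("oxidized", "custom")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- N_RESIDUES
  lognorm <- function(mean, cv) mean * exp(stats::rnorm(n, 0, cv) - cv^2 / 2)
  a_fast <- lognorm(scn$a_fast, 0.25)
  tau_fast <- lognorm(scn$tau_fast, 0.3)
  a_slow <- lognorm(scn$a_slow, 0.25)
  tau_slow <- lognorm(scn$tau_slow, 0.3)
  boost <- rep(1, n)
  boost[scn$loop_residues] <- scn$loop_boost
  boost[scn$cterm_from:n] <- pmax(boost[scn$cterm_from:n], scn$cterm_boost)
  a_slow <- pmin(a_slow * boost, 0.3)
  a_us <- rep(0, n); tau_us <- rep(NA_real_, n)
  exch <- vector("list", n)
  if (oxidized_like) {
    a_us <- lognorm(scn$ox_a_us, 0.25)
    tau_us <- lognorm(scn$ox_tau_us, 0.3)
    np <- length(scn$patch)
    a_us[scn$patch] <- stats::runif(np, scn$patch_a_us[1], scn$patch_a_us[2])
    tau_us[scn$patch] <- exp(stats::runif(np, log(scn$patch_tau_us[1]),
                                           log(scn$patch_tau_us[2])))
    ## disulfide formation also enhances ns motion near the cysteines
    cys_env <- c(38:55, 160:180)
    a_fast[cys_env] <- a_fast[cys_env] * 1.6
    for (r in scn$exchange_residues)
      exch[[r]] <- exchange_model(
        p_b = scn$p_b, k_ex = scn$kex,
        delta_omega = stats::runif(1, scn$dw_range[1], scn$dw_range[2]))
  }
  models <- lapply(seq_len(n), function(i) {
    a <- c(a_fast[i], a_slow[i], if (a_us[i] > 0) a_us[i])
    tau <- c(tau_fast[i], tau_slow[i], if (a_us[i] > 0) tau_us[i])
    motion_model(a, tau)
  })
  methyls <- NULL
  dosy <- NULL
  if (name == "dimer") {
    pos <- sort(sample(seq(5, n, by = 3), 40))
    pos <- unique(c(pos, 167, 168, 179, 183))
    s2 <- stats::runif(length(pos), scn$s2_core[1], scn$s2_core[2])
    s2[pos >= scn$tail_methyls_from] <- scn$s2_tail
    methyls <- data.frame(methyl = paste0("M", pos), residue = pos, s2 = s2,
                          stringsAsFactors = FALSE)
    dosy <- list(t_mid = scn$t_mid, dh = scn$dh_vant_hoff,
                 d_decamer = scn$d_decamer, d_dimer = scn$d_dimer,
                 t_ref = 298)
  }
  structure(list(name = name, seed = seed, noise = noise,
                 n_residues = n, models = models, exchange = exch,
                 patch = if (oxidized_like) scn$patch else integer(),
                 exchange_residues = if (oxidized_like)
                   scn$exchange_residues else integer(),
                 methyls = methyls, dosy = dosy,
                 tau_c = if (name == "dimer") scn$tau_c_dimer else NULL),
            class = "synthetic_truth")
}

## Noise-free forward rate of residue i under one condition, including any
## exchange contribution at the condition's spin-lock (additivity of the
## dipolar/CSA and exchange mechanisms is the generator's design premise).
.true_rate <- function(truth, i, cond, spin) {
  base <- if (cond$experiment == "R1") r1_rate(truth$models[[i]], spin, cond)
          else r1rho_mas(truth$models[[i]], spin, cond)
  em <- truth$exchange[[i]]
  if (!is.null(em) && cond$experiment == "R1rho")
    base <- base + (as.numeric(r1rho_laguerre(em, cond$nu_sl, 0, cond$b0)) -
                      em$r2_0)
  base
}

#' Noise-free forward rates for a whole scenario
#'
#' @param truth a [make_scenario()] result
#' @param conditions list of [experiment_condition()]
#' @param spin a [spin_interaction()]
#' @return matrix residues x conditions of true rates
#' @export
true_rates <- function(truth, conditions, spin = spin_interaction()) {
  out <- vapply(conditions, function(cond)
    vapply(seq_len(truth$n_residues), .true_rate, numeric(1),
           truth = truth, cond = cond, spin = spin),
    numeric(truth$n_residues))
  colnames(out) <- vapply(conditions, condition_key, "")
  out
}

#' Emit noisy rate tables for a scenario
#'
#' Gaussian noise of SD `truth$noise$rate` on every rate constant.
#'
#' @inheritParams true_rates
#' @param seed RNG seed for the noise (the only stochastic element)
#' @return a [rate_table()] covering all (residue, condition) pairs
#' @export
emit_rate_table <- function(truth, conditions, spin = spin_interaction(),
                            seed = 1L) {
  tr <- true_rates(truth, conditions, spin)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sig <- truth$noise$rate
  noisy <- tr + stats::rnorm(length(tr), 0, sig)
  rate_table(residue = rep(as.character(seq_len(nrow(tr))), times = ncol(tr)),
             rate = as.numeric(noisy),
             rate_err = rep(sig, length(noisy)),
             condition = rep(colnames(tr), each = nrow(tr)),
             experiment = paste0("synthetic_", truth$name))
}

#' Emit decay series (delay vs intensity) for a scenario
#'
#' Delays: 0.1-15 s for R1; 1-50 ms for NERRD R1rho; 1-200 ms for BMRD
#' R1rho. Relative Gaussian intensity noise `truth$noise$intensity`.
#'
#' @inheritParams emit_rate_table
#' @param n_delays delay points per series
#' @return list of [decay_series()]
#' @export
emit_decays <- function(truth, conditions, spin = spin_interaction(),
                        seed = 1L, n_delays = 8) {
  tr <- true_rates(truth, conditions, spin)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- list()
  for (j in seq_along(conditions)) {
    cond <- conditions[[j]]
    ## log-spaced delays, as usual for relaxation series: early points pin
    ## fast-relaxing residues, late points the slow ones
    delays <- if (cond$experiment == "R1") {
      exp(seq(log(0.1), log(15), length.out = n_delays))
    } else if (cond$nu_mas == 45e3) {
      exp(seq(log(1e-3), log(50e-3), length.out = n_delays))
    } else {
      exp(seq(log(1e-3), log(200e-3), length.out = n_delays))
    }
    for (i in seq_len(nrow(tr))) {
      ideal <- exp(-tr[i, j] * delays)
      noisy <- ideal + stats::rnorm(n_delays, 0, truth$noise$intensity)
      out[[length(out) + 1L]] <- decay_series(
        residue = as.character(i), delays = delays, intensities = noisy,
        intensity_errs = rep(truth$noise$intensity, n_delays),
        condition = cond)
    }
  }
  out
}

#' Emit triple-quantum buildup series for the dimer scenario
#'
#' 13 delays from 1 to 35 ms; relative Gaussian noise `truth$noise$tq`.
#'
#' @param truth a `"dimer"` scenario
#' @param geom a [methyl_geometry()]; defaults to the scenario's tumbling
#'   time and standard methyl geometry
#' @param delta_ext external-proton rate used for the truth (s^-1)
#' @param seed RNG seed
#' @return list of [tq_buildup()]
#' @export
emit_tq_buildups <- function(truth, geom = NULL, delta_ext = 10, seed = 1L) {
  if (is.null(truth$methyls)) stop("scenario has no methyl truth")
  if (is.null(geom)) geom <- methyl_geometry(tau_c = truth$tau_c)
  delays <- seq(1e-3, 35e-3, length.out = 13)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(seq_len(nrow(truth$methyls)), function(i) {
    eta <- s2_to_eta(truth$methyls$s2[i], geom)
    ideal <- tq_ratio_model(eta, delta_ext, delays)
    sig <- pmax(truth$noise$tq * abs(ideal), 1e-3)
    tq_buildup(truth$methyls$methyl[i], delays,
               ideal + stats::rnorm(13, 0, sig), sig)
  })
}

#' Emit temperature-series DOSY decays for the dimer scenario
#'
#' The apparent diffusion coefficient follows the two-state
#' decamer-dimer population average at each temperature, times the
#' Stokes-Einstein viscosity/temperature factor (so that
#' [viscosity_normalize()] recovers the size-only series). Relative
#' Gaussian intensity noise `truth$noise$dosy`.
#'
#' @param truth a `"dimer"` scenario
#' @param temperatures K
#' @param n_g gradient points per series
#' @param seed RNG seed
#' @return list of [dosy_series()]
#' @export
emit_dosy <- function(truth, temperatures = seq(298, 333, by = 5),
                      n_g = 8, seed = 1L) {
  if (is.null(truth$dosy)) stop("scenario has no DOSY truth")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  d <- truth$dosy
  g <- seq(0.05, 0.5, length.out = n_g)
  lapply(temperatures, function(tk) {
    p <- 1 / (1 + exp((d$dh / .const$gas_r) * (1 / d$t_mid - 1 / tk)))
    d_norm <- p * d$d_decamer + (1 - p) * d$d_dimer
    ## undo the Stokes-Einstein normalization to get the measured D
    d_meas <- d_norm / (viscosity_normalize(1, tk, d$t_ref))
    ser <- dosy_series(tk, g, rep(1, n_g))
    b <- .const$gamma_h^2 * g^2 * ser$delta_grad^2 *
      (ser$delta_big - ser$delta_grad / 3 - ser$tau_gap / 2)
    ideal <- exp(-d_meas * b)
    dosy_series(tk, g, ideal + stats::rnorm(n_g, 0, truth$noise$dosy),
                rep(truth$noise$dosy, n_g))
  })
}

#' Emit a synthetic chemical-shift table with known secondary structure
#'
#' Helix segments add +3 ppm to CA and -1 ppm to CB relative to the
#' random-coil reference; strands add -1.5/+1.5 ppm; a `marginal_helix`
#' segment adds only a fraction of the helix offsets (a marginally stable
#' helix that should classify as coil).
#'
#' @param random_coil reference table (`restype`, `ca`, `cb`)
#' @param helix,strand,marginal_helix integer vectors of residue numbers
#' @param marginal_fraction fraction of the helix offset for the marginal
#'   segment (default 0.125, i.e. ~ +0.5 ppm total)
#' @param seed RNG seed for the shift noise
#' @param noise_sd ppm noise on each shift
#' @return list with `shifts` (observed table) and `truth` (segment labels)
#' @export
emit_shift_table <- function(random_coil, helix = 15:25, strand = 60:66,
                             marginal_helix = 38:48,
                             marginal_fraction = 0.125,
                             seed = 1L, noise_sd = 0.05) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- N_RESIDUES
  types <- sample(random_coil$restype[random_coil$restype != "G"], n,
                  replace = TRUE)
  idx <- match(types, random_coil$restype)
  ca <- random_coil$ca[idx]; cb <- random_coil$cb[idx]
  lab <- rep("coil", n)
  ca[helix] <- ca[helix] + 3; cb[helix] <- cb[helix] - 1
  lab[helix] <- "helix"
  ca[strand] <- ca[strand] - 1.5; cb[strand] <- cb[strand] + 1.5
  lab[strand] <- "strand"
  ca[marginal_helix] <- ca[marginal_helix] + 3 * marginal_fraction
  cb[marginal_helix] <- cb[marginal_helix] - 1 * marginal_fraction
  lab[marginal_helix] <- "marginal_helix"
  shifts <- data.frame(residue = seq_len(n), restype = types,
                       ca = ca + stats::rnorm(n, 0, noise_sd),
                       cb = cb + stats::rnorm(n, 0, noise_sd),
                       stringsAsFactors = FALSE)
  list(shifts = shifts, truth = data.frame(residue = seq_len(n), label = lab))
}

#' Write every table of a scenario to a directory
#'
#' Forward-models every observable, adds the configured noise, and writes
#' the module-standard CSVs plus a `truth.json` that round-trips the
#' ground truth.
#'
#' @param truth a [make_scenario()] result
#' @param dir output directory (created if needed)
#' @param designs condition designs, see [default_designs()]
#' @param spin a [spin_interaction()]
#' @param seed RNG seed for all noise
#' @return invisibly, the vector of files written
#' @export
emit_tables <- function(truth, dir, designs = default_designs(),
                        spin = spin_interaction(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  all_conds <- c(designs$nerrd, designs$bmrd, designs$r1)
  rt <- emit_rate_table(truth, all_conds, spin, seed = seed)
  wr(as.data.frame(rt), "rates.csv")
  decays <- emit_decays(truth, all_conds, spin, seed = seed + 1)
  dd <- do.call(rbind, lapply(decays, function(s)
    data.frame(residue = s$residue, delay_s = s$delays,
               intensity = s$intensities, intensity_err = s$intensity_errs,
               condition = condition_key(s$condition))))
  wr(dd, "decays.csv")
  if (!is.null(truth$methyls)) {
    tq <- emit_tq_buildups(truth, seed = seed + 2)
    td <- do.call(rbind, lapply(tq, function(b)
      data.frame(methyl_id = b$methyl, T_s = b$delays, ratio = b$ratios,
                 ratio_err = b$ratio_errs)))
    wr(td, "tq_buildup.csv")
    dos <- emit_dosy(truth, seed = seed + 3)
    od <- do.call(rbind, lapply(dos, function(s)
      data.frame(temperature_k = s$temperature, g_tm = s$g,
                 intensity = s$intensities,
                 delta_grad_s = s$delta_grad, delta_big_s = s$delta_big,
                 tau_gap_s = s$tau_gap)))
    wr(od, "dosy.csv")
  }
  tj <- file.path(dir, "truth.json")
  write_truth(truth, tj)
  invisible(c(files, tj))
}

#' Serialize / restore a synthetic truth
#'
#' @param truth a `synthetic_truth`
#' @param path JSON file
#' @return `path` ([write_truth()]); a `synthetic_truth` ([read_truth()])
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    name = truth$name, seed = truth$seed, noise = truth$noise,
    n_residues = truth$n_residues,
    models = lapply(truth$models, function(m)
      list(amplitudes = m$amplitudes, taus = m$taus)),
    exchange = lapply(truth$exchange, function(e)
      if (is.null(e)) NULL else unclass(e)),
    patch = truth$patch, exchange_residues = truth$exchange_residues,
    methyls = truth$methyls, dosy = truth$dosy, tau_c = truth$tau_c)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  models <- lapply(obj$models, function(m)
    motion_model(num(m$amplitudes), num(m$taus)))
  exch <- lapply(obj$exchange, function(e) {
    if (is.null(e) || length(e) == 0) return(NULL)
    exchange_model(e$p_b, e$k_ex, e$delta_omega, e$r1, e$r2_0)
  })
  methyls <- NULL
  if (!is.null(obj$methyls) && length(obj$methyls))
    methyls <- data.frame(
      methyl = vapply(obj$methyls, function(r) r$methyl, ""),
      residue = vapply(obj$methyls, function(r) as.numeric(r$residue), 1),
      s2 = vapply(obj$methyls, function(r) as.numeric(r$s2), 1),
      stringsAsFactors = FALSE)
  dosy <- if (is.null(obj$dosy)) NULL else lapply(obj$dosy, as.numeric)
  structure(list(name = obj$name, seed = obj$seed,
                 noise = lapply(obj$noise, as.numeric),
                 n_residues = obj$n_residues, models = models,
                 exchange = exch, patch = num(obj$patch),
                 exchange_residues = num(obj$exchange_residues),
                 methyls = methyls, dosy = dosy,
                 tau_c = if (is.null(obj$tau_c)) NULL else as.numeric(obj$tau_c)),
            class = "synthetic_truth")
}

#' Synthetic stand-in decamer structure
#'
#' Builds an idealized toy decamer (ten identical subunits around a
#' five-fold ring, paired into dimers) carrying the geometric features the
#' structure metrics are tested against: the side-chain gamma atom of
#' residue 47 of each subunit sits a fixed distance (default 13 Angstrom)
#' from the Cys170 SG of its dimer partner, B-factors rise modestly toward
#' the C terminus and are low in the peroxidatic helix, and an optional
#' per-chain coordinate perturbation introduces subunit heterogeneity.
#' This is a synthetic stand-in, not a deposited structure.
#'
#' @param cp_cr_distance the inter-subunit 47gamma-170SG distance, Angstrom
#' @param heterogeneity SD (Angstrom) of per-chain random backbone
#'   perturbation (0 = identical subunits)
#' @param b_base,b_cterm B-factor baseline and C-terminal maximum
#' @param seed RNG seed for the heterogeneity
#' @return a [structure_model()] with chains A-J
#' @export
synthetic_decamer_structure <- function(cp_cr_distance = 13,
                                        heterogeneity = 0,
                                        b_base = 20, b_cterm = 45,
                                        seed = 1L) {
  n <- N_RESIDUES
  ## template subunit: compact coil of CA positions
  tpos <- seq_len(n)
  ca <- cbind(8 * cos(tpos * 0.65) + 3 * cos(tpos * 0.07),
              8 * sin(tpos * 0.65) + 3 * sin(tpos * 0.11),
              0.45 * tpos - 40)
  bfac <- b_base + (b_cterm - b_base) * pmax(0, (tpos - 165) / (n - 165))^2
  bfac[38:55] <- b_base * 0.8   # low-B peroxidatic helix
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  chains <- LETTERS[1:10]
  ring_r <- 45
  ## template subunit atom set (N, CA, C, O per residue), transformed
  ## rigidly per chain so that identical subunits superpose exactly
  offs <- matrix(c(-1.2, 0.3, -0.4,
                    0.0, 0.0,  0.0,
                    1.2, 0.4,  0.5,
                    1.8, 1.4,  0.2), 4, 3, byrow = TRUE)
  tmpl <- ca[rep(seq_len(n), each = 4), ] + offs[rep(1:4, n), ]
  restype <- rep("ALA", n); restype[47] <- "SER"; restype[170] <- "CYS"
  rows <- list()
  for (k in seq_len(10)) {
    phi <- 2 * pi * (ceiling(k / 2) - 1) / 5
    rot <- matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
                  3, 3, byrow = TRUE)
    ## dimer partners sit mirrored about the ring plane (a proper rotation
    ## by pi about the x axis, so handedness is preserved)
    flip <- if (k %% 2 == 0) diag(c(1, -1, -1)) else diag(3)
    xyz <- tmpl %*% t(rot %*% flip) +
      matrix(rep(c(ring_r * cos(phi), ring_r * sin(phi), 0),
                 each = nrow(tmpl)), nrow(tmpl), 3)
    if (heterogeneity > 0) {
      ## per-residue displacement (all backbone atoms of a residue move
      ## together, as a local conformational difference would)
      d <- matrix(stats::rnorm(3 * n, 0, heterogeneity), n, 3)
      xyz <- xyz + d[rep(seq_len(n), each = 4), ]
    }
    rows[[k]] <- data.frame(
      chain = chains[k], resno = rep(seq_len(n), each = 4),
      resid = rep(restype, each = 4),
      elety = rep(c("N", "CA", "C", "O"), n),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      b = rep(bfac, each = 4), occ = 1, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  ## place the gamma atoms: for each dimer (2k-1, 2k), the 47-gamma of one
  ## chain and the 170-SG of the partner lie cp_cr_distance apart
  for (k in seq_len(5)) {
    c1 <- chains[2 * k - 1]; c2 <- chains[2 * k]
    for (pair in list(c(c1, c2), c(c2, c1))) {
      ca47 <- atoms[atoms$chain == pair[1] & atoms$resno == 47 &
                      atoms$elety == "CA", c("x", "y", "z")]
      ca170 <- atoms[atoms$chain == pair[2] & atoms$resno == 170 &
                       atoms$elety == "CA", c("x", "y", "z")]
      dvec <- as.numeric(ca170 - ca47)
      dvec <- dvec / sqrt(sum(dvec^2))
      g47 <- as.numeric(ca47) + 1.9 * dvec
      g170 <- g47 + cp_cr_distance * dvec
      atoms <- rbind(atoms,
        data.frame(chain = pair[1], resno = 47, resid = "SER", elety = "OG",
                   x = g47[1], y = g47[2], z = g47[3],
                   b = bfac[47], occ = 1, stringsAsFactors = FALSE),
        data.frame(chain = pair[2], resno = 170, resid = "CYS", elety = "SG",
                   x = g170[1], y = g170[2], z = g170[3],
                   b = bfac[170], occ = 1, stringsAsFactors = FALSE))
    }
  }
  structure_model(atoms)
}
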