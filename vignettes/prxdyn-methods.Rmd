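---
title: "Models and methods behind prxdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prxdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

prxdyn implements the quantitative dynamics chain used to characterize the
redox-coupled dynamics of a decameric 2-Cys peroxiredoxin by MAS and
solution NMR. This vignette explains the models, the parameters that
matter, the numerical choices, and what the synthetic-data validation does
and does not demonstrate.

## The relaxation model

Every rate expression rests on the model-free spectral density with the
2/5 normalization,

    J(w) = (2/5) * sum_k a_k tau_k / (1 + (w tau_k)^2),

where each internal motion contributes an amplitude `a_k = 1 - S_k^2`
(unitless, 0 = rigid) and a correlation time `tau_k` (seconds). In
solution an overall isotropic tumbling time combines harmonically with
each internal time. Mixing spectral-density conventions is the classic
factor-of-5/2 error, so the constant is defined once (`J_NORM`) and used
everywhere. Two interactions drive amide ¹⁵N relaxation: the ¹H–¹⁵N
dipolar coupling (bond length 1.02 Å) and the ¹⁵N CSA (−172 ppm, unique
axis taken collinear with the bond). These are standard amide values; they
are parameters of `spin_interaction()` and can be overridden.

### R1rho under MAS and the NERRD effect

Under magic-angle spinning the static secular `4 J(0)` term of transverse
relaxation is redistributed over spectral densities at the combination
frequencies of the rotor and spin-lock:

    R1rho = R_hf + (d^2/2 + 2 c^2/3) *
            [ w1 (J(wr - w1') + J(wr + w1')) + w2 (J(2wr - w1') + J(2wr + w1')) ]

with sideband weights `w1 = 1/3` and `w2 = 1/6`. These weights are the
powder averages of `|d^2_{m0}(theta_magic)|^2` for the m = ±1 and ±2 MAS
sidebands; the package freezes them as constants and keeps a provenance
test that recalibrates them against `redfield_r1rho()`, a numerical
second-order evaluation for a symmetric two-site jump: per crystallite,
the rank-2 spatial tensor in the rotor frame is Fourier-decomposed over
the MAS sidebands, each component's fluctuation amplitude is weighted by a
Lorentzian at `m*wr - w1`, and the result is averaged over a deterministic
quasi-uniform spherical grid (300 orientations by default; the average
changes by <1% on grid doubling, which `check_convergence` enforces). The
analytic expression and the oracle agree to better than 0.5% over
correlation times from 100 ns to 100 μs and spin-locks up to 41 kHz at
45 kHz MAS.

The consequence probed experimentally: motions slower than about 1 μs make
R1rho rise as the spin-lock approaches the rotor frequency (a non-flat
NERRD profile), while any motion faster than ~100 ns gives a profile flat
to within 1%.

### Exchange

Two-state chemical exchange adds a shift-modulation contribution that is
*quenched* by the spin-lock. Three evaluators are provided, in increasing
generality: the fast-exchange closed form
`R_ex = pA pB dw^2 k_ex / (k_ex^2 + w1^2)`, the Laguerre (second-order)
approximation valid off resonance and outside fast exchange, and a 6×6
Bloch–McConnell propagator (x, y, z magnetization of both states,
exchange, offsets, spin-lock) that serves as ground truth. The propagator
extracts the rate from a log-linear fit of the magnetization projected on
the effective-field axis over the final 80% of the lock, avoiding the
initial transients; a residual above tolerance flags a non-exponential
decay. The three agree to <5% in their shared regime.

`fit_dispersion_joint()` fits multiple residues' dispersion curves with a
global `k_ex` (optionally a global `p_b`; fixed at 0.05 by default since
fast exchange determines only the product `pA pB dw^2`), per-residue `dw`
and an uninterpreted plateau, with eight log-spaced `k_ex` starts in
10²–10⁵ s⁻¹.

**A deliberate caveat.** With the study's spin-lock grid (2.3–15 kHz) and
`k_ex` near 10³ s⁻¹, the lowest effective field (ω₁ ≈ 1.4·10⁴ rad/s) is
already an order of magnitude above `k_ex`, so the curve shape carries
almost no information about `k_ex` itself: only the amplitude combination
is well determined. The Cramér–Rao bound at the generator's truth exceeds
100% relative uncertainty for any plausible ¹⁵N shift difference. The
joint fitter recovers `k_ex` exactly from noiseless curves (the optimizer
is not the limitation), but at realistic noise its `k_ex` estimate should
be treated as order-of-magnitude only. The tests assert the noiseless
identifiability and report the noisy-recovery statistics honestly.

## Detectors

Instead of forcing a single correlation time, a set of measured rates is
re-parameterized over a z-grid, z = log10(tau/s), from −12 to −3 in steps
of 0.05 (spanning ps to ms). The sensitivity matrix holds the rate each
experiment would show for a unit-amplitude motion at each grid point; its
row-normalized SVD defines the measurable subspace. Detector shapes are
linear combinations of the first m right singular vectors, optimized
jointly (BFGS with analytic gradients) to minimize their second moments
about their centers under non-negativity, with the sum of shapes pinned to
one at the centers. With that normalization, and because the response fit
uses the same row scaling as the SVD, the response to a unit-amplitude
motion at a detector center is exactly one — responses read as motional
amplitudes.

The localization functional (second moment under non-negativity and the
partition constraint) is this package's own choice; detector equivalence
with other implementations is asserted at the level of window placement
and response recovery, not shape by shape.

**Windows and the blind spot.** The 8-experiment reference design (seven
R1rho at 45 kHz MAS, 10–41 kHz spin-lock, plus one R1) senses ps–ns motion
through R1 (window near z ≈ −8.7) and μs motion through the near-rotary
terms (windows between z ≈ −5.7 and −4.2). No experiment separates
10–300 ns: the sum of detector shapes cannot exceed ~0.9 near z = −6 and
falls to ~0.15 near z = −7 *within any subspace this design spans*, so
amplitude recovery there is biased low by design, not by implementation.
The package therefore reports windows honestly (where the shape sum is
within 10% of one) and the validation probes recovery at the detector
centers; degradation outside the windows is asserted in the tests rather
than hidden.

## The NERRD-corrected dispersion pipeline

`run_pipeline()` chains: (1) weighted mono-exponential decay fits (profile
method: the amplitude is eliminated analytically, leaving a 1-D
minimization in the rate; Monte-Carlo rate errors); (2) detector analysis
of the NERRD+R1 rates; (3) back-calculation of the dipolar/CSA
contribution *at the dispersion experiment's own MAS frequency* (55 kHz,
vs 45 kHz in the NERRD design — the near-rotary terms depend on the rotor
frequency, so re-evaluating the reconstruction at the target condition is
the physically correct choice) and subtraction from the measured rates,
plus a constant 5 s⁻¹ plateau so the fitter never sees negative rates;
(4) significance flagging; (5) the joint exchange fit of flagged residues,
restricted to spin-locks of at least 2 kHz (below which incompletely
suppressed dipolar dephasing inflates R1rho).

Design choices that deserve justification:

- **Correction subspace (`m_correction = 6`) vs reporting detectors
  (`m_detectors = 4`).** Reconstructing rates at a different MAS frequency
  needs the design's full information content: with four detectors the
  reconstruction bias leaves ~2 s⁻¹ of spurious dispersion for strongly
  moving residues, comparable to real exchange dispersions. Six singular
  vectors reduce the noiseless bias below 0.5%.
- **Two flag sets.** Microsecond bond reorientation makes R1rho *rise*
  with spin-lock strength; exchange makes it *fall*. Non-flat NERRD
  profiles are therefore flagged per residue by a chi-square test against
  a flat model (alpha = 10⁻³), which reaches every patch member regardless
  of its amplitude; exchange-type dispersion is flagged by the 3×SD rule
  on the difference between the corrected low-field (2.3 kHz) and
  high-field (15 kHz) rates, computed over all residues with no iterative
  trimming.
- **Reliability gate (`backcalc_max = 15` s⁻¹).** Residues whose measured
  high-field rate (where exchange is quenched) exceeds this bound are
  dominated by dipolar/CSA relaxation; their corrected curves cannot reach
  exchange-scale precision and they are excluded from the 3×SD population
  (in practice such residues are broadened beyond detection anyway). They
  remain in the tables, flagged.
- **Order safety.** A corrected rate table carries a provenance flag and a
  second application of the correction is refused.

## Methyl order parameters and diffusion

The 3Q/SQ buildup ratio follows the two-parameter form
`(3/4) eta tanh(sT) / (s - delta tanh(sT))`, `s = sqrt(eta^2 + delta^2)`,
cross-checked against a matrix-ODE integration of the two-manifold rate
equations. `eta` converts to the methyl-axis order parameter via
`S2 = eta / ((9/10) P2(cos 90°)^2 (mu0 gamma_H^2 hbar / (4 pi r_HH^3))^2 tau_c)`
with `r_HH = 1.813 Å` and the overall tumbling time supplied externally
(27 ns for the dimer, from TRACT). `delta` absorbs external protons and is
fitted, never interpreted.

Diffusion decays follow Stejskal–Tanner with bipolar correction,
`I = I0 exp(-D gamma_H^2 g^2 delta^2 (Delta - delta/3 - tau/2))`, with the
reference design delta = 3.2 ms, Delta = 400 ms, tau = 0.1 ms. Normalized
coefficients (`D * eta(T)/eta(T_ref) * T_ref/T`, heavy-water viscosity
interpolated linearly in log eta) feed a two-state van 't Hoff sigmoid
`D(T) = p D_oligomer + (1-p) D_dissociated`; the fit multi-starts over the
sign of the van 't Hoff slope so relabeling the states converges to the
same midpoint. A series whose spread is within noise, or below 5% of the
separation between the pure-state coefficients, is flagged transition-free
rather than fitted.

## Chemical shifts and structure metrics

Secondary shifts are `(dCA - dCA_rc) - (dCB - dCB_rc)` against a
random-coil table consumed as input (recomputing a neighbor-corrected
predictor is out of scope; two reference tables ship as fixtures).
Classification uses ±0.7 ppm sustained over four residues — conventional
thresholds, not taken from any specific study; a marginally stable helix
(~+0.5 ppm) deliberately classifies as coil. Structure metrics (distances
with a residue-type-aware "gamma" atom selection so that a C47S
reduced-mimic resolves to OG, backbone B-factor profiles, pairwise Kabsch
superposition RMSD on common residues) operate on a light atom-table
container filled from PDB/mmCIF files.

## The synthetic-data generator

`make_scenario()` encodes the study conditions as ground truth over 196
residues:

- **reduced**: two motional components everywhere (1−S² = 0.015 at 3 ns;
  0.033 at 55 ns, log-normal residue-to-residue scatter), ns-mobile loop
  residues (30, 31, 117, 167; ×2.5) and a mobile C-terminal stretch from
  residue 141 (×2.6). Flat NERRD profiles by construction.
- **oxidized**: adds a global microsecond component (0.0026 at 10 μs), a
  contiguous high-amplitude patch over the peroxidatic helix (residues
  38–55; 1−S² = 0.03–0.1 at 5–50 μs), mildly enhanced fast motion around
  both cysteines, and a five-residue exchange cluster at the dimer–dimer
  interface (74, 76, 78, 80, 82; k_ex = 1100 s⁻¹, p_b = 0.05, Δω drawn
  from 8–11 ppm).
- **dimer**: ~44 methyls with core S² in 0.6–0.9 and a disordered tail
  (S² = 0.1 from residue 167), tumbling at 27 ns, and a decamer–dimer
  transition with midpoint 315 K (van 't Hoff enthalpy 150 kJ/mol,
  D = 4.5·10⁻¹¹ and 7.7·10⁻¹¹ m²/s for decamer and dimer at 298 K).
- **custom**: an oxidized-type scenario with any constant overridden
  (e.g. a patch-only dataset).

The amplitude constants were calibrated once, at design time, so that the
emitted cohorts reproduce the reference cohort statistics — reduced R1rho
mean/median 3.9/2.8 s⁻¹ at 10 kHz spin-lock and R1 0.056 s⁻¹; oxidized
R1rho mean 9.6 s⁻¹ (2.5× the reduced mean) and R1 0.062 s⁻¹ — and were
frozen. The exchange cluster's Δω range was chosen so its dispersions
(~2–5 s⁻¹) stand clearly above the 3×SD detection line, as in the
reference data; at smaller Δω the cluster sits at the detection threshold.
Decay delays are log-spaced (0.1–15 s for R1, 1–50 ms for NERRD, 1–200 ms
for the dispersion experiment), the standard design that keeps
fast-relaxing residues determined. Gaussian noise is the only stochastic
element (defaults: σ = 0.3 s⁻¹ on rates, 2% on intensities, 5% on 3Q/SQ
ratios, 3% on DOSY intensities), and every table is reproducible from
(scenario, seed).

**What passing tests show — and what they do not.** The generator
forward-models observables through the same family of physical expressions
the fitters invert (with the numerical oracles as the independent
referees), so recovery tests demonstrate the internal consistency and
statistical calibration of the chain, not its robustness to physics the
model omits: anisotropic overall diffusion, ¹³C relaxation pathways,
cross-correlated relaxation, three-state exchange, coherent (dipolar
dephasing) contributions at weak spin-locks, and temperature-dependent
sample changes are all outside the model. Real spectra also lose residues
to broadening; the generator keeps every residue observable and instead
relies on the pipeline's reliability gate.

Problem sizes used throughout the validation: 196-residue scenarios, 15
conditions, 20-replicate recovery studies for k_ex and the diffusion
midpoint, 100 replicates for the methyl cross-correlated rate, 300-point
powder grids. These keep a full validation run around a minute on one CPU.

## Known limitations

- The packaged sequence and decamer structure are synthetic stand-ins
  whose aggregate properties match the published values (documented in
  their help pages); they are not database entries.
- `k_ex` from the joint dispersion fit is weakly identified at the
  reference study's spin-lock range (see above).
- Amplitudes recovered by the detectors are reliable only inside the
  detector windows; the 10–300 ns decade is a blind spot of the reference
  design.
- Isotropic overall tumbling only; solution-state R2 assumes a single
  global correlation time.
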