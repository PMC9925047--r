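---
title: "Models and methods in pcfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pcfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcfkit)
```

`pcfkit` simulates and analyzes patch-clamp fluorometry (PCF) experiments:
simultaneous recordings of ionic current and of a fluorophore that reports
voltage-sensor conformation, the configuration used to dissect gating of
the human voltage-gated proton channel (HV1). This vignette documents the
models, the numerical choices, the defaults and their rationale, and the
limits of what the synthetic-data tests demonstrate.

## The kinetic model

Gating is a continuous-time Markov process on a connected graph of channel
states. Each directed transition carries a rate law

$$k_{ij}(V) = k_{ij}(0)\, e^{-z_{ij} V / kT},$$

with $k_{ij}(0)$ the rate at 0 mV (ms⁻¹) and $z_{ij}$ the partial charge
(e₀) moved during the transition. Under this sign convention a transition
that accelerates with depolarization carries negative $z$; scheme files
must therefore store signed charges per transition. The thermal voltage
$kT/e_0$ is 25.693 mV at the default 298.15 K (room temperature) and is
configurable through `model_constants()`.

Occupancies obey the master equation
$dP_i/dt = \sum_{j \ne i}(P_j k_{ji} - P_i k_{ij})$, i.e.
$\dot P = Q^{\mathsf T} P$ for the generator matrix built by
`build_generator()` (off-diagonal $(i,j) = k_{ij}$, diagonal = −row sum).
Observables are

* current: $I = \gamma_{ch} N (V - V_{rev}) P_o + \gamma_{leak}(V - V_{rev}^{leak})$,
  with $P_o$ the summed occupancy of conducting states, the channel term
  in pS·mV (converted to pA) and the leak in nS·mV;
* fluorescence: $F = \sum_i P_i f_i$ with per-state weights $f_i$ (a.u.),
  averaged over each camera exposure.

### Propagation

Voltage-clamp protocols here are step protocols, so within each epoch the
generator is constant and the exact solution is the matrix-exponential
propagator applied to the epoch's entry occupancy. `propagate()` evaluates
it through the eigendecomposition of $Q^{\mathsf T}$, which turns the whole
epoch into one dense matrix product and makes multi-second tails at 20 kHz
cheap. When the eigenvector matrix is ill-conditioned (reciprocal
condition number below 1e−10, as can happen for nearly defective
generators) the implementation falls back to a stepped matrix-exponential
walk on the same grid via `Matrix::expm`. Epoch entry states are always
computed from the exact end-of-epoch propagator, so splitting an epoch at
any interior time leaves the trajectory unchanged (verified to 1e−10 in
the tests). Probability conservation is structural (rows of $Q$ sum to 0)
and is asserted to 1e−9 over >10⁵ time points; an independent fixed-step
fourth-order Runge–Kutta integrator written in the test helpers, not the
package, reproduces the propagator to 1e−6 on random 3–6-state schemes.

### The built-in sequential scheme

`scheme_hv1_sequential()` ships a three-state chain C1 ⇄ C2 ⇄ O3 (O3
conducting; fluorescence weights 0, 1, 1 so activated states are bright)
whose defining property is a C2→C1 backward step far slower than channel
closing O3→C2. Consequences at the −60 mV holding potential:

* the current tail decays essentially mono-exponentially with the fast
  eigenrate (~141 ms by default) — the slow mode contaminates the tail by
  <5% because the C2⇄O3 equilibrium lies strongly toward C2 at −60 mV;
* the fluorescence off-response is bi-exponential: a small fast lag plus
  a dominant slow (~6 s) return of the sensor, because F tracks C2+O3,
  which only drains through the slow step.

The numeric rate constants are **package defaults, not fitted values**:
they were chosen once so that at the reference gradient ΔpH = 1 the
steady-state open-probability midpoint sits near +24 mV with apparent
charge ≈ 1.3 e₀, the tail time constant at −60 mV is ≈ 141 ms, and the
slow off-component falls in the seconds range. In this strict linear
chain the F-V curve necessarily sits tens of mV negative to the G-V
curve; real HV1 data show the two nearly superimposed, so the default
scheme reproduces the kinetic signature of deactivation, not every
equilibrium feature. The same applies to the `scheme_allosteric()` 2×2
ladder, which is a configurable topology approximation.

### pH-gradient dependence

No mechanistic pH dependence is imposed. A condition's gradient
ΔpH = pHo − pHi shifts every voltage-dependent rate along the voltage
axis by a configurable `dv_per_dpH` (default 40 mV per unit, the
empirical rule for proton channels), implemented as
$k_0 \to k_0 e^{-z\,\Delta V/kT}$. Individual rates can additionally be
overridden per condition (`rate_overrides`), which is how the stronger
pH sensitivity of the slow backward step is expressed: shrinking that one
rate reduces the slow off-amplitude realized within a recording window,
the behaviour the acceptance suite checks.

## Trace analysis

* **Conductance**: chord conductance $G = I/(V - V_{rev})$ from the mean
  current over an end-of-pulse window (default: final 10% of the pulse;
  configurable). Sweeps at $V_{rev}$ are excluded with a warning. $V_{rev}$
  comes from recording metadata; `estimate_vrev()` interpolates the I-V
  zero crossing when no measured value exists.
* **Boltzmann fits**: the activation form
  $y = A/(1 + e^{-q(V - V_{1/2})/kT})$, in which positive $q$ describes
  curves that rise with depolarization. The decreasing-form convention
  (positive exponent) paired with positive printed charges is internally
  inconsistent, so the package standardizes on the activation form; every
  benchmark (V½, q) pair is direction-consistent under it. Initialization:
  $V_{1/2}$ from the linear-interpolated half-maximum crossing, $q = 1$,
  with five perturbed restarts (Levenberg–Marquardt via `minpack.lm`)
  before failure is declared. Normalization divides by the maximum point
  by default; dividing by the fitted amplitude is available because either
  reading of "normalized" is defensible, and the two agree to 1e−3 on
  saturating curves.
* **ΔF/F₀**: $100\,(F_i - F_0)/F_0$ with $F_0$ the first frame by default
  (a pre-pulse-mean baseline is available for noisy data and recorded in
  the output's attributes). The measure is invariant to rescaling the raw
  trace, which the tests assert to 1e−12.
* **Exponential kinetics**: activation fits use
  $A_{ss}(1 - e^{-(t - t_0)/\tau})$ on the second half of the pulse by
  time (fraction configurable); $t_0$ is fixed at the pulse start, not
  free, since it is defined by the protocol. Flat traces return a
  `degenerate` flag rather than a spurious τ. Off-responses use a sum of
  two exponentials with components reported fast-first; a
  single-exponential fit of the same window is always computed and the
  AIC difference reported, so mono-exponential inputs are detected
  (vanishing second amplitude or a degeneracy warning when the time
  constants are within 3× of each other). Multi-start initial guesses
  cover a fast×slow grid over the window's decades — necessary because
  the fast component of the built-in scheme's off-response has only
  percent-level (and negative) amplitude.
* **τ(V)**: log-linear least squares on $\ln\tau$ vs $V$ for
  $\tau(V) = \tau(0)e^{qV/kT}$, which is exact on noiseless data and
  agrees with a direct nonlinear fit to 0.5%.
* No multiple-testing correction is applied anywhere; the summary
  statistics mirror single planned comparisons.

## Spectra

Spectrograph line scans enter as wavelength/intensity tables
(400–700 nm). Background from a cell-free region on the same grid is
subtracted pointwise, retaining negative residuals; implicit
interpolation across mismatched grids is refused. Peak finding is a plain
argmax within a band, optionally after a small moving-average smooth — no
lineshape fitting, since only peak positions and heights are quantified.
Default bands, inferred from the fluorophores' stated peak positions
(~480 nm Anap, ~610 nm mCherry): 440–540 nm and 590–640 nm;
configurable. The Anap/mCherry peak ratio is invariant to global
intensity scaling.

`welch_t_from_summary()` computes Welch's t and Satterthwaite df directly
from printed means/SEMs/n — it matches a raw-data `t.test()` exactly when
the summaries come from the same groups. `ph_invariance_test()` fits
`intensity ~ pH + cell` by `stats::aov` — pH as the factor of interest,
cell as a blocking factor; the two-way design with seven pH levels yields
the factor df of 6. Cells missing a pH level are dropped listwise with a
warning. Its type-I error calibrates to the nominal 5% in seeded null
simulations.

## Synthetic data

Generators are pure functions of (parameters, seed): identical seeds give
bit-identical output. Defaults mirror the acquisition chain of the
experiments they emulate — 20 kHz current sampling behind a 5 kHz
anti-alias filter, camera frames at 10–25 Hz with exposure up to the
frame interval, test families −100…+120 mV in 20 mV steps with a 45 s
inter-sweep interval, and pH conditions drawn from pHo/pHi ∈
{5.5/5.5, 6.5/5.5, 7.5/5.5, 7/7}. The anti-alias stage is a 4-pole
low-pass Bessel filter (hand-built from the standard analog prototype
poles and discretized with the bilinear transform, with prewarping, since
no installed package ships a Bessel prototype); it is applied causally
and preserves DC to 0.1%. Current noise is additive Gaussian per sample;
fluorescence noise is additive Gaussian per frame by default
(camera-read dominated) with an optional shot-noise mode — no noise
spectrum is imposed beyond that. Synthetic emission spectra are two
Gaussian bands (widths 35 and 20 nm — package choices; only the peak
positions are benchmark-anchored) truncated at three widths so the
default search bands see one band each, plus an optional fixed fractional
bleed-through of the mCherry band representing direct excitation, not a
photophysical model.

What passing tests on these fixtures show — and what they do not: the
generators share the observable equations with the simulator, so
round-trip tests demonstrate that the analysis pipeline inverts the
stated model at the stated noise levels; they do not demonstrate
robustness to proton depletion, series-resistance error, drift,
photobleaching or cell-to-cell variability beyond a scalar amplitude,
none of which are modelled.

## Problem sizes and numerical tolerances

The shipped test suite simulates at 0.5–20 kHz over 0.4–23.5 s sweeps and
uses 100 random schemes for the propagator cross-check, 150–200 Monte
Carlo replicates for fit-recovery suites and 600 replicates for the ANOVA
calibration — sizes chosen so the full suite completes in well under a
minute per file while keeping Monte-Carlo standard errors small relative
to the asserted tolerances. Key tolerances: propagator vs oracle 1e−6;
two-state closed forms 1e−10; probability conservation 1e−9; Boltzmann
refit self-consistency 1e−8; scale invariances 1e−12.

## Pipeline and provenance

`run_config()` + `run_simulation()` + `run_analysis()` orchestrate
multi-condition studies: one recording per condition row, written as
long-format delimited tables with a YAML manifest recording options,
per-condition seeds (derived deterministically from the master seed) and
the package version. Per-sweep fit failures are collected and reported,
not fatal. `reproduce_figure()` tabulates computed-vs-printed benchmark
values; without source recordings it degrades to a synthetic demo that
regenerates each benchmarked quantity noiselessly from its printed
parameters and re-analyzes it, flagging every row `"demo"`. Long-format
delimited text is the single on-disk format for traces; no binary
container is used. The package exposes its functionality as R functions
rather than a shell executable — scripts composing them (see
`scripts/acceptance.R`) are the batch interface.

## Known limitations

* Deterministic (mean-field) master-equation simulation only: no
  single-channel stochastic gating, no gating-current observable.
* No proton depletion/accumulation, series-resistance or leak-subtraction
  modelling; sweep exclusion beyond a current-magnitude rule is out of
  scope.
* The built-in schemes are qualitative: their rate constants are package
  defaults tuned to the deactivation signature, and the sequential
  topology cannot superimpose F-V on G-V.
* Spectral analysis assumes pre-extracted line scans; no image
  segmentation or wavelength calibration.
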