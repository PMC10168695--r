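---
title: "Modelling and measuring voltage-dependent polyamine block of CP-AMPARs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring voltage-dependent polyamine block of CP-AMPARs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyblock)
```

## The problem

GluA2-lacking, calcium-permeable AMPA receptors (CP-AMPARs) are blocked by
intracellular polyamines in a strongly voltage-dependent way: depolarization
drives the polycationic blocker into the pore, suppressing outward current.
Weakly permeant blockers (spermine) can escape to the extracellular side at
strongly positive potentials, so their block is partially relieved and the
I-V relationship is *doubly rectifying*; non-permeant blockers (NASPM,
certain polyamine toxins) give essentially complete suppression of outward
current — *full inward rectification*. Quantifying this behaviour involves a
standard set of measurements: rectification indices, Boltzmann fits of
conductance-voltage (G-V) curves, voltage-independent potency (IC50 at
0 mV), block and recovery kinetics, and synaptic-event (mEPSC) analysis.
`polyblock` implements that measurement stack together with a generative
model of the underlying channel behaviour, so every stage of the analysis
can be validated against a known ground truth without any recorded data.

## The kinetic model

The simulator uses a five-state ensemble scheme:

```
        beta * glu           delta(V)
   C  <------------>  O  <------------>  D
        alpha                gamma
                      |
             kon(V)   |   koff(V) + kperm(V)
                      v
        alpha*(1-glu) |            trap_unblock_rate
   OB  ------------->  CB  ----------------------------> C
```

- `C`, `O`, `D`: closed, open and desensitized states of the unblocked
  receptor. Opening requires glutamate (`beta * glu`, `glu` in [0, 1]).
- `OB`: open-blocked — the blocker occupies the pore of an open channel.
  Blocking is bimolecular, `kon(V) = kon0 · [B] · exp(V / (2·h_block))`;
  unblocking to the intracellular side is `koff(V) = koff0 ·
  exp(−V / (2·h_block))`; permeation (escape to the outside) is
  `kperm(V) = kperm0 · exp(V / h_perm)`.
- `CB`: trapped block. A blocked channel that closes on glutamate removal
  (rate `alpha`) traps the blocker; it escapes only slowly
  (`trap_unblock_rate`, default 2.04e-4 ms⁻¹, i.e. a ~4.9 s time constant).
  This trapped pool is what produces the characteristic biphasic
  paired-pulse recovery at +60 mV: a fast component (recovery from
  desensitization, `1/gamma`) and a slow component (relief of trapped
  block).
- Closed-state block is exposed as `closed_block_factor` (scaling of
  `kon` in the closed state) but **defaults to 0**: with any appreciable
  closed-state blocking rate, the entire closed population becomes trapped
  during inter-pulse gaps at +60 mV, which would erase the partial fast
  recovery that the paired-pulse phenomenology requires. The parameter is
  there for exploring closed-channel block, not part of the default
  conditions.

The voltage dependence of block is split symmetrically between `kon` and
`koff` (the factor 2 in `h_block`) so that the open-channel equilibrium is
analytically exact: for a non-permeant blocker the equilibrium unblocked
fraction is a Boltzmann,

`u(V) = 1 / (1 + exp((V − Vb)/kb))`, with `kb = h_block` and
`Vb = h_block · ln(koff0 / (kon0·[B]))`.

That identity is what makes the whole analysis chain testable: the
G-V/Boltzmann pipeline must recover `Vb` and `kb`, and the potency chain
must recover `IC50,0mV = koff0/kon0` and a slope of `−h_block·ln 10` mV per
decade of concentration.

Integration is by matrix-exponential propagation of the state vector over
each sample interval (eigendecomposition of the generator matrix, with a
scaling-and-squaring fallback). Rates are piecewise constant within protocol
segments, so this is exact, stiff-safe, and conserves total probability to
machine precision; the simulator verifies conservation to 1e-8 at every
sample and signals an integration failure otherwise.

## Default parameters and where they come from

Gating defaults (`gating_params()`): `beta = 10`, `alpha = 2` ms⁻¹ (fast,
near-saturating activation by 10 mM glutamate), `delta = 0.165`,
`gamma = 0.0175` ms⁻¹. These place the no-blocker decay time constant at
−60 mV near 5.7 ms with a steady state of roughly 10% of peak, and recovery
from desensitization at `1/gamma ≈ 57 ms` — so residual depression is
visible at a 150 ms inter-pulse interval but recovery is complete by
~400 ms. The desensitization rate carries a weak voltage dependence,
`delta(V) = delta · exp(−V/delta_evolt)` with `delta_evolt = 430 mV`, so
that without blocker the decay is modestly *slower* at +60 than at −60 mV
(≈7.3 vs 5.7 ms), as observed for these receptors; this is the one
deliberate extension beyond a voltage-independent gating scheme, and
`delta_evolt = Inf` disables it. Intrinsic (polyamine-independent) outward
rectification of the open channel is a conductance factor
`rho(V) = 1 + exp((V − 60)/35)`, roughly doubling conductance at +60 mV.

Blocker presets:

- `naspm_params()` (non-permeant): `kon0 = 0.0045 µM⁻¹ms⁻¹`,
  `koff0 = 0.0045 ms⁻¹`, `h_block = 12 mV`, `kperm0 = 0`. The on-rate is
  pinned by the observed acceleration of the current decay at +60 mV with
  10 µM blocker (≈1.7–1.8 ms against ≈5.7 ms without); the off-rate is then
  set so that steady-state outward current at 10 µM is nearly abolished
  (steady-state rectification index ≈ 0.05), which corresponds to an
  `IC50,0mV` of 1 µM. At 100 µM the equilibrium unblocked fraction at
  +60 mV is 7e-5 — the full-rectification regime.
- `spermine_params()` (permeant): `kon0 = 0.01`, `koff0 = 0.77`,
  `kperm0 = 3.92e-4 ms⁻¹`, `h_block = 10`, `h_perm = 6 mV`. These values
  were chosen jointly so that (i) the simulated ramp I-V is doubly
  rectifying with an interior current minimum near +30 mV, and (ii) the
  unblocked fraction at +60 mV is ≈0.30, which puts scaled mEPSC amplitudes
  near the detection threshold and reproduces partial event thinning at
  positive potentials (frequency-weighted RI ≈ 0.2). A known limitation:
  with a single five-state parameter set, the doubly-rectifying shape
  forces the permeant preset's midpoint toward 0 mV at 100 µM — i.e. the
  permeant preset is *less* potent than the non-permeant one, which
  inverts the real potency order of spermine and NASPM. The presets are
  phenotype emulators, not affinity measurements.

mEPSC generation: homogeneous Poisson events (default 5 Hz), lognormal
amplitudes at −60 mV (mean 36 pA, CV 0.3), a difference-of-exponentials
waveform (`tau_r = 0.2 ms`, `tau_d = 1.2 ms`, unit peak) and additive white
Gaussian noise (default SD 3.5 pA, the typical background-noise SD of
whole-cell recordings of this kind). At holding potentials other than
−60 mV the event amplitude is scaled by
`u(V) · |(V − v_rev)/(−60 − v_rev)|` and signed by the driving force, so a
saturating non-permeant blocker pushes every outward event far below any
realistic threshold.

## Ramps: quasi-static treatment

Voltage ramps (default 100 mV/s, 2 kHz sampling, cyclothiazide-like regime
with desensitization absent) are simulated with the *equilibrium* block
fraction at each voltage rather than the kinetic scheme. At 100 mV/s the
blocker equilibrates far faster than the command voltage moves through the
steep part of the block curve, so the quasi-static approximation is
accurate; the modest accumulation of block that a slow unblocking step can
produce during real ramps is deliberately not emulated. Leak is linear
(default 1 nS through 0 mV) and removed by interleaved control sweeps, as
in the measurement convention.

## Analysis conventions and numerical choices

- **Rectification index (ramp)**: mean current over 15 consecutive samples
  centred on the sample nearest +60 mV, divided by the magnitude of the
  same average at −60 mV. The count is sample-based (configurable); at
  2 kHz and 100 mV/s it spans ≈0.75 mV, and with other sampling rates the
  voltage span changes accordingly. At a grid edge the window shifts inward
  rather than failing, so ramps that end exactly at +60 mV are usable.
  The numerator keeps its sign, so a linear I-V through 0 mV gives +1 and a
  fully blocked outward limb gives 0.
- **Reversal potential**: single zero crossing within ±20 mV of 0 mV,
  linearly interpolated between the bracketing samples after a 15-sample
  running-mean smooth. If noise still flickers the sign within a ≤5 mV
  band, the root of a least-squares line through that band is used; sign
  changes spread wider than 5 mV are an error. For deeply blocked curves
  the outward limb carries no usable crossing, so the potency pipeline
  takes the reversal from the polyamine-free reference instead.
- **G-V construction**: `G = I/(V − v_rev)`, dropping points within 5 mV of
  the reversal (the division amplifies noise without bound as the driving
  force vanishes; 5 mV bounds that error). Division by the polyamine-free
  conductance removes the intrinsic rectification `rho(V)`; normalization
  is to the most negative retained voltage, where relief of block is
  maximal. Per-sweep normalization precedes any averaging across sweeps.
- **Boltzmann fits**: Levenberg–Marquardt least squares (`minpack.lm`),
  relative tolerance 1e-10, up to 5 jittered restarts. Slopes are left
  unconstrained; initialization is `Vb` at half-maximal conductance,
  `kb = +10 mV`, and for the double model `Vp = Vb + 60`, `kp = −10`,
  `Gmax,p = 0.3·Gmax` (the permeation limb rises with voltage, hence the
  negative slope initialization). Poorly constrained fits surface through
  the convergence flag and residual sum of squares — never by silently
  dropping data; exclusion decisions stay with the caller.
- **Decay fits**: fitted from the in-window peak to the end of the agonist
  window (at least 20 samples) with a free offset absorbing the steady
  state. `tau_w` follows the amplitude-weighted formula exactly; single-
  and double-exponential `tau` values are pooled into one column by the
  voltage-profile table. Model order is caller-specified, with an `"auto"`
  option using an F-test at alpha = 0.01 — note that on noiseless
  simulated traces the F-test always prefers two components, so tests of
  monotone tau-voltage relationships fix the order to 1.
- **Steady state**: mean over the final 10% of the agonist window (the
  window length is a convention; the occupancy has settled well before it
  under default rates).
- **Recovery fits**: `1 − Ff·exp(−t/tau_f) − Fs·exp(−t/tau_s)` with
  fractions bounded in [0, 1] and time constants positive.
- **mEPSC detection**: baseline is a 50 ms running median; the trace is
  boxcar-smoothed over 0.3 ms before thresholding. Smoothing is essential,
  not cosmetic: white noise sampled at 20 kHz crosses a 2.5 SD threshold
  thousands of times per 40 s, and a ~6-sample boxcar moves the effective
  threshold to >6 smoothed-noise SDs while attenuating a 36 pA event by
  only ~20%. A crossing within 2 ms of the previous candidate, or before
  the signal has re-armed below half the threshold, merges into that
  candidate (hysteresis — otherwise an event's own decay fluctuating
  through the threshold is double-counted). Amplitude is the extremum of
  the processed trace within 10 ms of the crossing. The monotonic-rise
  flag tolerates counter-movements up to one noise SD; the clean-decay
  flag requires no new crossing within 5 decay time constants of the peak.
  Events are aligned on their threshold crossing for averaging; the
  average is re-baselined on the early pre-event window because the
  running median is slightly biased near large events. Frequency counts
  all detected events; the mean waveform uses only clean-flagged events.
- **Noise SD**: single-sided Gaussian fit to an all-point histogram of a
  500 ms stretch — only the half of the distribution on the side away from
  event polarity is fitted, so synaptic contamination of one tail does not
  inflate the estimate. Records with fewer than 10 events per 40 s at
  −60 mV (rate-prorated) fail QC, with the reason reported.
- **Welch tests** accept `(mean, SEM, n)` summaries as well as raw
  samples, so published group summaries can be re-tested directly; the
  paired form is the one-sample t-test on differences (variance pooling is
  moot on differences). p-values recomputed from rounded summaries land
  within a few thousandths of raw-data values, not exactly on them.
- **BCa bootstrap**: Efron bias correction (`z0` from the fraction of
  resample statistics below the observed value, clamped to
  `[1/(B+1), B/(B+1)]`), jackknife acceleration (group-wise leave-one-out
  for the unpaired difference), endpoints by type-7 quantiles; default
  5000 resamples, seeded. An exhaustive mode enumerates all `n^n`
  one-sample resamples for tiny problems, which makes the implementation
  checkable against direct enumeration. At n = 10 per group the nominal
  95% interval covers a true mean difference about 91% of the time — the
  well-known mild anticonservatism of BCa at small n, and the calibration
  the test suite asserts.
- **Box summaries**: type-7 quartiles; whiskers at the most extreme
  observations within 1.5 IQR of the box,
  `min(x[x > Q1 − 1.5·IQR])` and `max(x[x < Q3 + 1.5·IQR])`.

## File formats and reproducibility

Sweeps are columnar text (`time_ms`, `current_pA`, `voltage_mV`) with a
JSON sidecar carrying protocol metadata and a mandatory units declaration;
round trips are lossless to better than 1e-9. All modules work in the
canonical units mV/pA/ms. `run_pipeline()` ties simulation and analysis
stages into file-to-file runs that embed the fully resolved configuration,
package version and seeds in their outputs; identical configuration and
seed reproduce identical artifacts bit for bit, and a failing sweep is
logged and skipped rather than aborting a run. An HDF5 container rendition
and Axon Binary Format import are not provided.

## What the simulations do and do not establish

The test suite exercises every analysis stage against the generator's
analytic ground truth: Boltzmann fits on simulated ramps recover `Vb`
within fractions of a millivolt (noiseless) or ±2 mV (G-V noise SD 0.02,
median over 10 replicates), the four-concentration potency chain recovers
`IC50,0mV` within a few percent, decay fits recover the block-accelerated
time constants, recovery fits recover the trapped-block time constant
within 25%, and the event pipeline detects essentially every event ≥3×
threshold at ≤2 Hz while returning an RI of exactly 0 in the saturating
non-permeant regime. Problem sizes in the suite (10–40 s synthetic records,
2.8k-sample ramps, 500-replicate coverage studies) were chosen as the
smallest that make those properties statistically sharp.

What passing these tests does *not* show: the generator's noise is white
and Gaussian (no 1/f component, no stimulus artifacts, no series-resistance
error), events never overlap pathologically, gating is a three-state
skeleton without modal or single-channel behaviour, and the permeant preset
trades potency realism for I-V shape. Results on real recordings therefore
inherit the usual caveats of threshold detection and unconstrained
nonlinear fitting, and the exclusion-style diagnostics (convergence flags,
QC reasons) are reported precisely so that such decisions remain visible.
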