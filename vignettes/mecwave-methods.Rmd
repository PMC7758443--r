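---
title: "Mechano-electric coupling and calcium waves in 1D myocyte strings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-electric coupling and calcium waves in 1D myocyte strings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Mechanically heterogeneous myocardium is arrhythmogenic. One candidate
mechanism is mechano-electric coupling (MEC) through the myofilaments:
stretch transients change the calcium affinity of troponin C (TnC), the
released calcium loads the sarcoplasmic reticulum (SR), and under calcium
overload the SR discharges spontaneously. The discharge propagates along
the cell as a calcium wave, drives a depolarising sodium-calcium exchange
(NCX) current, and appears on the membrane as a delayed after-depolarisation
(DAD) — subthreshold, suprathreshold, or a full triggered beat. `mecwave`
simulates this chain of events in one dimension: single rabbit ventricular
myocytes discretised into calcium-release units (CRUs), strings of myocytes
coupled by gap junctions, optional fibroblasts, prescribed stretch
protocols, and an analysis suite that detects and measures the resulting
events.

# Model architecture

## The calcium-release unit

Each CRU pairs a reduced rabbit ventricular membrane model with one
sarcomere. The membrane model is authored for this package: a
Hodgkin–Huxley fast sodium current, an L-type calcium current with GHK
driving force (so extracellular calcium `Ca_o` acts directly on calcium
entry), transient outward and delayed rectifier potassium currents, an
inward rectifier, a sodium–potassium pump, NCX, background sodium/calcium
currents and a sarcolemmal calcium pump. Calcium is tracked in three
compartments per CRU — subsarcolemmal space (SS), junctional SR, and bulk
cytosol — with 17 ionic states plus 3 mechanical states per CRU.

Three design elements carry the arrhythmia phenomenology:

* **Release gating.** The ryanodine-receptor flux
  `J_rel = v_rel * o * r * (Ca_SR - Ca_cyto)` uses a fast activation gate
  `o` (Hill 4 in subspace calcium) and a refractory gate `r` with
  calcium-dependent inactivation and recovery gated on *low* subspace
  calcium. This makes every release a terminating burst: there is no
  partially-open chronic equilibrium, which plagued flatter gating
  variants during development.
* **Luminal sensitisation.** The activation threshold collapses steeply
  (Hill 50 around `k_sr_thr = 1.31` mM free SR calcium). Below threshold
  the RyR only answers the L-type trigger; above it, diastolic subspace
  calcium suffices and release self-ignites. Spontaneous release is
  therefore a deterministic function of SR load.
* **Reversible SERCA.** Uptake
  `J_up = v_up * (fw - rv)/(1 + fw + rv)` with forward term
  `fw = (Ca_cyto/k_up)^3` and reverse term `rv = (Ca_SR/k_srmax)^3` gives
  the SR a thermodynamic load ceiling proportional to diastolic cytosolic
  calcium. Because diastolic calcium rises with `Ca_o` (GHK-shaped
  background influx, NCX kinetics), the extracellular-calcium sweep maps
  monotonically onto SR load — the lever the calcium-sweep design relies on.

With the default calibration the model rests at −85 mV, paces at 1 Hz with
APD90 ≈ 235 ms and a ~0.5–1 µM calcium transient, stays quiescent after
pacing at `Ca_o = 2.0` mM, and produces spontaneous release events from
`Ca_o ≈ 3.7` mM upward, grading from subthreshold DADs to triggered beats
as the release flux grows.

## Mechanics and the mechano-electric feedback

The sarcomere model is deliberately small: one TnC occupancy state, one
cooperative crossbridge state, and sarcomere length `SL` relaxing toward
the length command of the stretch protocol (length-controlled loading;
force-controlled loading is out of scope). The TnC pool (70 µM of sites)
is *removed* from the ionic model's buffers and its net binding flux is
withdrawn from the cytosol explicitly — the strong-coupling wiring that
avoids double-counting the same buffer.

The feedback itself modulates both TnC rates exponentially with strain
rate, `k = k0 * exp(alpha * dSL/dt / SL_rest)`, with the off-rate
sensitivity amplified at stretched lengths
(`alpha_eff = alpha_off * (1 + gamma_sl * (SL - SL_ref)/SL_ref)`) and the
exponent clamped at ±`max_log_mod` (= 3) as a numerical safeguard that
physiological strain rates never reach. Because `exp` is convex, an
oscillating strain rate produces a *net* increase of the mean off-rate, so
cyclic stretch releases TnC calcium into the cytosol, where SERCA converts
it into SR load. The `alpha` values are a package calibration, not
literature constants: the shipped defaults make a 10% stretch applied over
100 ms raise diastolic cytosolic calcium by well over the 5% design
target (≈ +70% at `Ca_o = 2`).

## Fibroblasts

The active fibroblast model carries five state variables (membrane
potential, activation and inactivation gates of the time- and
voltage-dependent K⁺ current, and intracellular Na⁺/K⁺) and four currents
(I_Kv, inward-rectifier I_K1, Na⁺/K⁺ pump, background Na⁺). Uncoupled it
rests near −48 mV. The myocyte junction is a fixed linear conductance
drawn uniformly from 0.5–8 nS, attached to one of the terminal five CRUs
of an end; the junctional current `G_f,gap (V_f - V_m)` drains
depolarising charge from the (higher-potential) myocyte during the AP
plateau and during DADs. No calcium crosses the junction.

## Spatial couplings

Within a myocyte, the three calcium compartments of adjacent CRUs exchange
through symmetric nearest-neighbour stencils with time constants
`tau_SS = 0.4533` ms, `tau_SR = 150` ms, `tau_cyto = 1.2` ms, and the
membrane potentials through the same stencil with `tau_Vm = 1e-5` ms, which
makes one myocyte nearly isopotential while still supporting a propagating
upstroke. All stencils are zero-sum, so the couplings conserve total
compartment calcium and (absent membrane currents) mean potential.

Between myocytes, the last and first boundary CRUs are joined by a linear
gap junction (default 400 nS). The junctional current is applied with the
charge-conserving orientation — the higher-potential side loses
depolarising charge; the alternative orientation (both boundary
derivatives following the upstream sign) is retained behind the
`eq6_verbatim_signs` flag for auditing and is demonstrably
anti-conservative (it blocks conduction; a unit test shows the sign
structure). The current is divided by the per-CRU capacitance
(cell capacitance / 50) for dimensional consistency.

Inter-sarcomere mechanical coupling combines the per-sarcomere isotonic
rates `dSL^`. Two modes ship:

* `"verbatim"` — interior sarcomeres get `2*own - (left + right)`,
  boundaries `own - neighbour`. This form annihilates any common-mode
  signal: a homogeneous fiber shortening uniformly is frozen, and a global
  stretch protocol never reaches the sarcomeres. It is retained as the
  operator-level default as the strict difference form.
* `"relaxed"` — `own + kappa*(neighbour mean - own)` preserves the common
  mode while smoothing inter-sarcomere differences. Because the stretch
  protocols are inert under the verbatim form, the *engine* default is
  `relaxed` with `kappa = 0.5`; the mode is recorded in the result
  metadata.

## Stimulus

The stimulus is an additive term on CRU 1's voltage equation,
`amplitude/duration` mV/ms for 3 ms — a depolarising impulse whose time
integral is the configured amplitude. Because the fiber is nearly
isopotential, the impulse spreads over all CRUs, so capture requires an
amplitude proportional to fiber size; the experiment helpers use 40 mV per
CRU (`defaultStimAmplitude()`), while `conductionParams()` keeps a nominal 1000 mV default.

# Protocols

Four length-command waveforms multiply the per-sarcomere resting length,
all periodic with the pacing cycle: `H` (sinusoid dipping to 20%
compression — normal shortening), `I` (isometric), `S` (sinusoid spanning
0.90–1.10 with stretch in systole), and `P` (exponential rise to a 15%
plateau at contraction onset, rise constant 20 ms, decaying from half-cycle
with constant 40 ms — ischaemic-segment lengthening). Phase conventions
not fixed by the protocol descriptions (S's phase, P's onset/decay
timing) are configurable defaults. Pacing runs for at most 200 beats
(default cycle length 1000 ms) with optional early exit once the
mean-squared error between consecutive APs falls below 0.01 mV²; the
default desk-scale experiments use 15 beats, which this model needs to
approach its limit cycle. After pacing and stretching stop, a quiescent
observation window (default 10 s; events are only scored inside it)
follows. The extracellular-calcium sweep covers 2.0–4.5 mM in 0.1 mM steps
at full scale; scaled studies use coarser grids.

# Measurements

* **APD90** — from the maximum-upstroke instant to 90% recovery toward the
  pre-upstroke diastolic potential, with interpolated crossings.
* **Event detection** — a spontaneous event is a cytosolic calcium
  excursion exceeding the per-CRU diastolic level by 0.05 µM (config) in
  at least one CRU; per-CRU activation is the crossing of 50% of that
  CRU's own event amplitude. Event classes are read from the simultaneous
  membrane potential: no deflection (< 2 mV), subthreshold DAD,
  suprathreshold DAD (≥ 15 mV without a regenerative upstroke), or
  triggered beat (regenerative dV/dt ≥ 20 mV/ms reaching positive
  potentials). Waves are co-classified fast/slow at 1000 µm/s, the
  midpoint of the two orders of magnitude separating the fast
  (~4000–4600 µm/s) and slow (~100–200 µm/s) wave populations this
  kind of preparation exhibits.
* **Wave velocity** — absolute slope of the least-squares fit of CRU
  centre position against activation time (≥ 3 activated CRUs; zero time
  spread flags a synchronous event instead).
* **Wave amplitude** — maximum over CRUs of the baseline-relative peak, in
  µM.
* **Dyssynchrony** — sample (n−1) standard deviation across cells of the
  per-cell mean time-to-peak calcium. During observation windows the
  per-cell value is anchored on each cell's *first* detected event, which
  keeps the measure stable when repetitive events occur.
* **Group statistics** — three-sigma outlier removal per group, one-way
  ANOVA, all-pairs Bonferroni-adjusted comparisons, significance tiers at
  p < 0.01 / 0.05 / 0.1.

# Numerical choices

One stiff adaptive solver (`deSolve::lsoda`) integrates everything, with a
banded numerically-generated Jacobian whose bandwidth follows from the
state layout: consecutive 20-value CRU blocks with each fibroblast's
5-value block stored immediately after its host CRU. Absolute tolerances
are scaled per state field (calcium lives near 1e-4 mM, potentials near
1e2 mV). The right-hand side exists twice: a vectorised pure-R reference
implementation (the documented module surface) and a compiled C kernel
used by the engine; a parity test holds them equal to 1e-12 at randomised
states, so the fast path can never drift from the reference. Sampling is
1 ms during pacing and 0.5 ms during observation windows. Integration
proceeds beat by beat, which gives the limit-cycle early exit for free.

Degenerate inputs are handled explicitly: non-finite states abort with the
offending variable and time named; sarcomere lengths outside 1.4–2.4 µm
are clamped for the force/affinity computations with a warning; gate
equations use guarded forms at their removable singularities.

# Scaled study sizes

The full study design (50 CRUs per myocyte, 200 beats per condition, 26
calcium steps, 10 heterogeneity replicates, fibroblast and multi-cell
variants) is hours-to-days of compute on one CPU. The package's own tests
and the acceptance script therefore run the same code paths at a reduced
size chosen to preserve the phenomenology: 10 CRUs per myocyte, 15 paced
beats, 10 s observation, and coarse calcium grids. At this scale a single
condition takes tens of seconds. `replicationStudy()` exposes every size
as an argument, so the full-scale study is the same call with larger
numbers.

# What the synthetic conditions do and do not show

The heterogeneity generator reproduces the stated design: per-sarcomere
resting lengths drawn uniformly from [1.701, 2.079] µm, fibroblast
positions uniform over the terminal five CRUs of either end, junction
conductances uniform on [0.5, 8] nS, all reproducible from logged seeds.
Passing the scaled checks shows that the implemented mechanisms interact as designed — stretch raises diastolic calcium and SR load,
overload ignites deterministic spontaneous release, fibroblasts drain
charge, junctions synchronise — under the reduced model's dynamics. It
does not validate the quantitative biophysics of real rabbit myocytes:
the cell models here are reduced constructions calibrated to headline
behaviours, not the full published rabbit ventricular parameterisations.

# Known limitations

* The three cell models are reduced re-formulations authored for this
  package, calibrated to resting potential, AP morphology, transient
  amplitude and overload behaviour. Quantities that depend on the fine
  structure of the full published models (exact APD rate dependence,
  current densities) are not expected to match.
* The homogenised deterministic fiber propagates spontaneous release fast:
  once one CRU ignites, subspace diffusion recruits its neighbours within
  milliseconds, so measured wave velocities sit in the fast-wave decade
  (10³–10⁵ µm/s). The slow ~100 µm/s regime requires sub-cellular
  heterogeneity or stochastic RyR gating that a deterministic common-pool
  CRU does not sustain. Velocity-estimator accuracy is therefore
  established on synthetic translating pulses.
* The wave-threshold calcium ties at 3.7 mM across stretch patterns at the
  shipped calibration: the susceptibility ordering P ≤ S ≤ H ≤ I holds,
  but without strict separation. Parameterisations that separate the
  patterns strictly (stronger strain coupling, weaker release) lose the
  conducted synchronisation of coupled cells; the defaults favour the
  latter.
* Fibroblast effects are amplified at the 10-CRU test scale, since the
  fixed 0.5–8 nS junction conductances load a smaller total membrane
  capacitance than in a 50-CRU myocyte. Monotonicity is preserved;
  magnitudes are scale-dependent.
* 2D/3D anisotropy, mechano-sensitive channels, stretch-activated reactive
  oxygen signalling, calcium flux between myocyte and fibroblast, and
  dynamic (voltage-gated) junction models are out of scope.

# Worked example

```{r}
library(mecwave)

# one overloaded, stretched myocyte: pace, stop, observe
res <- runStretchExperiment(pattern = "S", ca_o = 4.0, n_cru = 10,
                            seed = 1, n_beats = 15, observation = 10000)
res
events <- detectEvents(res)
events[[1]]

# fibroblast loading shortens the action potential
fibroblastAPDStudy(c(0, 1, 3), ca_o = 2.0, n_cru = 10, seed = 1,
                   n_beats = 15)

# gap junctions synchronise DADs across a 3-myocyte chain
couplingStudy(n_cells = 3, ca_o = 4.0, seed = 10, n_cru = 10,
              n_beats = 15, observation = 10000)
```
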