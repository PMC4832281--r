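---
title: "Decoding calcium signatures through CaM–CAMTA binding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding calcium signatures through CaM-CAMTA binding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camdecode)
```

## The model

Cytosolic calcium signals in plants are stimulus-specific time courses —
oscillatory spike trains, single transients, prolonged plateaus — and the
cell must translate their shape into the right transcriptional response.
`camdecode` implements one complete route for that translation: Ca²⁺ binds
calmodulin (CaM), Ca²⁺-loaded CaM binds the transcription factor CAMTA, and
the fully loaded 4Ca²⁺–CaM–CAMTA complex regulates target genes.

The binding layer is a lattice of 19 state variables: CaM with 0–2 Ca²⁺ on
its N-terminal lobe and 0–2 on its C-terminal lobe (macroscopic sequential
binding per lobe, each lobe independent of the other's occupancy), each
state free or CAMTA-bound, plus free CAMTA. The 33 mass-action reactions
split into twelve Ca²⁺ steps in the free layer, twelve in the CAMTA-bound
layer, and nine CaM–CAMTA association steps. Ca²⁺ itself is a *clamped
input*: the model is driven by measured or constructed signatures and does
not feed back on them (no buffering of Ca²⁺ by CaM is modelled), which is
appropriate when the signature is an experimental observable rather than a
state to be predicted.

### Parameters and their derivation

Measured anchors (all dissociation constants in μM, on-rates in μM⁻¹ s⁻¹):

| step | K_d | k_on |
|---|---|---|
| first Ca²⁺, C lobe | 10 | 4 |
| second Ca²⁺, C lobe | 0.925 | 10 |
| first Ca²⁺, N lobe | 25 | 100 |
| second Ca²⁺, N lobe | 5 | 150 |
| Ca²⁺-loaded CaM + CAMTA | 1.2 × 10⁻³ | 1 (adjustable) |

Two dimensionless cooperativity parameters complete the picture. `p = 0.1`
makes apo-CaM bind CAMTA more weakly than any Ca²⁺-loaded CaM
(K_d(apo) = K_d/p); `p` must lie in (0, 1] and the constructor rejects
anything else. `q = 1` locates that cooperativity entirely in the off-rate
(k_on(apo) = k_on/q); `q = 1/p` would locate it entirely in the on-rate.

Everything else is forced by thermodynamics. At equilibrium the product of
equilibrium constants around any closed reaction cycle must equal one (the
Wegscheider condition), otherwise the cycle would sustain a perpetual flux.
Applied to each square cycle of the lattice this (i) copies every
free-layer Ca²⁺ constant onto its bound-layer counterpart, except (ii) the
two Ca²⁺ steps leaving the apo-CaM–CAMTA complex, whose K_d is multiplied
by `p`. For those two forced steps the split between on- and off-rate is
not determined by thermodynamics; we keep k_on at the free-layer value and
let k_off absorb the change, consistent with the `q = 1` reading that
cooperativity acts through unbinding. `wegscheider_check()` re-derives
nothing: it walks all 20 elementary square cycles of the final table and
reports the cycle products, so an externally edited (or deliberately
perturbed) parameter set is caught.

The totals are the remaining degrees of freedom. Total CAMTA defaults to
its reference value of 10 μM. Total CaM is not fixed by the anchored set;
it defaults to 10 μM and `calibrate_cam_total()` pins it against an
expression anchor (below).

### Gene expression

mRNA obeys a single delayed balance driven by the active complex
M = [M22X](t − τ): production `k1 + k2·(M/k4)^n / (1 + (M/k4)^n)` for
activated genes (`k2/(1 + (M/k4)^n)` for repressed ones) minus first-order
decay `k3·[mRNA]`. The delay τ (default 600 s) stands for assembly of the
transcriptional machinery. Because expression does not feed back on
binding, the delay is implemented exactly by time-shifting the input
rather than by a delay-differential solver; for `t − τ` before the
simulation start the input is the control level. The defaults
(k₁ = 5 × 10⁻⁶, k₂ = 5 × 10⁻² μM s⁻¹, k₃ = 3.75 × 10⁻⁴ s⁻¹,
k₄ = 1.1 × 10⁻² μM, n = 2) give a baseline mRNA of k₁/k₃ ≈ 0.013 μM, a
maximal steady-state induction of (k₁+k₂)/k₁ = 10001-fold, and an mRNA
lifetime 1/k₃ ≈ 44 min — the slow memory that integrates fast complex
excursions. k₄, the DNA-binding affinity of the active complex, is the key
decoding parameter: an order of magnitude in either direction moves a
signature from strongly inducing to effectively silent.

## Numerical choices

*Integration.* Both stages use LSODA (`deSolve`), an adaptive
stiff-capable integrator, at relative and absolute tolerance 10⁻⁵ for the
binding network; the network is genuinely stiff (off-rates span 1.2 × 10⁻³
to 2.5 × 10³ s⁻¹). Tightening the tolerances does not change the reported
folds, which we verified during development by re-running the pipeline at
10⁻⁸/10⁻¹².

*Square-wave inputs.* Traces built by `piecewise_signature()` carry their
exact switch times and levels, and `simulate_binding()` restarts the
integrator at every switch with the calcium level clamped constant over
the segment, so discontinuities are never smeared by interpolation. For
generic traces the input is linearly interpolated between samples and held
constant beyond the trace ends — which is why generated traces always end
on their baseline level.

*Forcing resolution.* The active complex rises and falls on a ~0.5 s
timescale at spike edges (set by k_on·[Ca²⁺] of the lobe steps). The
complex trajectory that forces the expression stage is therefore sampled
at 0.05 s (`out_dt`); coarser sampling visibly biases the expression folds
for short-period signatures because the linear interpolant clips the spike
shoulders. The expression stage itself evolves on the 1/k₃ timescale and
is output at 0.5 s.

*Steady states.* `steady_state()` relaxes the clamped network from a
canonical partition (all CaM apo and free, all CAMTA free) over
successively longer horizons until max |d/dt| < 10⁻¹⁰ μM s⁻¹; the clamped
lattice with its two conservation laws has a unique positive equilibrium,
so the start is immaterial. `equilibrium_oracle()` reaches the same point
algebraically: every species is apo-CaM times a product of ca/K_d and
[X]/K_d factors along any path (path-independent by the Wegscheider
condition), leaving one scalar conservation equation solved by bracketed
root finding. The two routes share only the reaction table; their
agreement to 10⁻⁶ relative on randomized parameters is part of the test
suite and is the package's central numerical cross-check.

*Non-negativity.* States are clipped at zero when an integrator restart
would otherwise inherit a tiny negative concentration (within tolerance of
zero); mRNA likewise.

## Conventions the data do not fix

*Phase of the square wave.* The defining relation of a square-wave
signature — average A = (t_max·ca_max + t_min·ca_min)/T — fixes the dwell
times but not where within a cycle the high phase sits. The package lays
out the low phase first, so a spike develops after stimulation onset
rather than the trace opening mid-spike; this matches how square-wave
reconstructions of measured spike trains align to the recordings from
which their parameters are taken. With the calibrated CaM total the
convention reproduces the expected ordering and spacing of
period-dependent expression folds, which the mirror-image convention
distorts for long periods (the final spike then sits a full low-phase
earlier, and its contribution has decayed by an extra factor exp(k₃·t_min)
at readout).

*Control level.* The resting calcium level defaults to 0.10 μM — the
minimum of the reference oscillatory signature — and is configurable; all
fold changes are taken against the steady state at this level.

*Binding-step labels.* The nine CaM–CAMTA association steps share one
affinity for all eight Ca²⁺-loaded states, so the mapping of individual
labels to states is a documented convention (canonical occupancy order)
with no dynamical consequence.

*Readout.* Expression folds are reported 1 h after signature onset
(configurable), with ≥ 1.5-fold flagged as induced.

## Calibrating the total CaM concentration

Total CaM is the one concentration the anchored parameter set leaves free.
`calibrate_cam_total()` finds the value at which a chosen anchor signature
produces a chosen expression fold at readout, by bracketed root finding on
log₁₀(CaM_total) after verifying at the bracket endpoints that the readout
fold is increasing in the total. Against the reference anchor — the
period-40 s square wave (A = 0.16 μM, 0.52/0.10 μM levels, 400 s) decoding
to 6.0-fold at 1 h — the calibration lands at ≈ 10.4 μM, reassuringly close
to the 10 μM reference CAMTA total. The calibration is exercised in both
directions in the tests: a total recovered from a readout generated at a
known total matches it to better than 1%.

## What the synthetic generators do and do not emulate

`piecewise_signature()` reconstructs square waves exactly from summary
parameters (average, extremes, period, duration) and satisfies the
defining average identity to 10⁻⁹ by construction. `synthetic_signature()`
provides smooth stand-ins for the three experimental signature classes:
sin²-bump spike trains (oscillatory), a linear rise with exponential
return (transient), and a saturating rise to a held plateau (prolonged),
with optional seeded Gaussian noise. These are shape emulations, not fits
to any recorded trace: tests built on them demonstrate the model's
*properties* (super-linear amplification, affinity-dependent decoding,
history accumulation) but not agreement with any particular recording.
Analyses whose absolute numbers depend on digitized experimental traces
are correspondingly out of scope.

## Problem sizes used in the tests

The routine suite uses short signatures (two spikes, 20-min readout) for
pipeline tests and the full reference protocol (400 s signatures, 1-h
readout, CaM calibration) for the end-to-end checks; the randomized
oracle-equivalence property uses 20 parameter draws. These sizes keep the
full suite in the low minutes while still exercising every code path at
the reference conditions.

## Known limitations

- Ca²⁺ is clamped: CaM buffering of calcium, and any feedback of the
  readout on the signature, are outside the model.
- One CaM pool, one CAMTA pool: no CaM-like proteins, CAMTA isoforms,
  post-translational modification, or nuclear/cytosolic
  compartmentalization.
- The expression stage is the simplest possible: one promoter input, no
  translation layer, no stochasticity, fixed delay.
- Lobe independence and the equal-affinity assumption for loaded-CaM
  binding are modelling choices that keep the parameter count at what the
  data can support, not measured facts about every intermediate state.
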