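---
title: "A charge-difference myocyte model of ischemia and reperfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A charge-difference myocyte model of ischemia and reperfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(reperfusim)
```

## The model

`reperfusim` simulates a single guinea-pig ventricular myocyte through
three protocol phases — pre-ischemic pacing, total ischemia with an
isolated extracellular space, and reperfusion — with the membrane
potential computed by the *charge-difference* formulation: `V` is an
affine function of the valence-weighted intracellular content (free ions,
free and buffer-bound protons, hydroxide, bicarbonate, total myoplasmic
and SR calcium, and a generic metabolic anion), not the integral of the
membrane currents.  The offset of that affine map is calibrated once so
that the shipped initial state sits exactly at its stated potential
(−77.00 mV); after that, every flux in the model moves ions and therefore
moves `V`.  A property test verifies that the two bookkeeping routes — the
charge sum and −(1/C_m)·∫ΣI dt — agree to integration tolerance (the
residual is a small fraction of the current turnover and halves with the
Euler step), including through the imposed ischemic acidification.

The electrophysiology is a Luo–Rudy-dynamic-class current set (fast and
late Na⁺, L- and T-type Ca²⁺ with GHK driving terms, the delayed and
inward rectifiers, plateau K⁺, an ATP-inactivated K⁺ current with
Ferrero-type nucleotide gating, Na⁺/K⁺ pump, Na⁺/Ca²⁺ exchanger,
sarcolemmal Ca²⁺ pump, and Na⁺/Ca²⁺/Cl⁻ backgrounds), coupled to an SR
with a reduced thermodynamic-cycle SERCA (flux = 0.00820 × cycle rate),
a calcium-triggered release channel with proton inhibition, and
transfer/leak pathways.  pH regulation comprises the four acid
transporters (NHE, NBC, CHE, AE), CO₂/bicarbonate hydration kinetics in
both compartments, and two-component intrinsic buffering whose
concentrations and pK values are shared between the intracellular and
extracellular compartments.  Osmotic water flux moves volume between the
myoplasm and the extracellular space; amounts, not concentrations, are
the conserved carriers across volume changes, which makes the
two-compartment conservation laws exactly testable.

Modifications stated for this parameterization and applied here: the
proton block of the Na⁺/Ca²⁺ exchanger uses pK 7.0 and Hill coefficient
0.75; the exchanger amplitude is 0.60 × its published scale; the
sarcolemmal Ca²⁺ pump maximum is 1.65 µA/µF; fast-Na conductance drops
from 16.0 to 14.4 mS/µF during ischemia; the late-Na scale is 0.0007
normally; the stimulus is −80 µA/µF for 0.5 ms at 3 Hz; the integrator is
forward Euler at Δt = 0.005 ms.

### The NHE and its allosteric regulation

The sodium–proton exchanger is stimulated by intracellular protons (Hill
coefficient 3) and inhibited by extracellular protons (Hill
coefficient 1), with one shared proton binding constant (pK 6.7) for both
sides.  Its flux is multiplied by the inhibition scale of the experiment
grid (1.0, 0.5 or 0.0) from the configured onset (reperfusion start,
mid-ischemia — exactly ischemia onset + half the ischemic duration — or
ischemia onset).

### The pump's pH sensitivity

The Na⁺/K⁺ pump carries Na⁺ i / K⁺ o / voltage / phosphometabolite
dependences and a proton-inhibition factor (pK 6.9, Hill 2, normalized to
unity at the pre-ischemic pH 7.15): the pump is nearly silent at the
end-ischemic pH of 6.0 and recovers steeply as reperfusion pH rises,
which is what couples impaired pH recovery to sodium overload.  The pH-clamp experiment replaces only
the pH the pump senses during reperfusion with the pre-ischemic value,
leaving every other component on the true pH.

## The protocol as the study conditions

The protocol engine *is* the data generator: there is no randomness
anywhere in the pipeline, and identical configurations are bit-identical
within a build.  Default conditions are 5 min pacing, 20 min ischemia,
10 min reperfusion:

* **Ischemia.** Intracellular pH is prescribed as an exponential approach
  from its end-of-pre-ischemia value (continuity anchor) to 6.0 with a
  5-min time constant; ATP and PCr decay along imposed schedules (ATP to
  25 % over the 20-min reference with exponent 1.5; PCr exponentially to
  a 5 % floor, τ = 2.5 min); intracellular osmolarity rises linearly at
  1 mOsm/min; the extracellular compartment is fully isolated, so K⁺,
  Na⁺, Ca²⁺, Cl⁻, CO₂ and bicarbonate accumulate or deplete only through
  membrane transport, amplified by extracellular shrinkage from osmotic
  water influx; extracellular pH is dynamic (transporter flux + CO₂
  accumulation + intrinsic buffering).
* **Reperfusion.** Extracellular pH relaxes to 7.40 with τ = 1.5×10⁵ ms
  (within 0.01 units in roughly ten minutes); the six extracellular
  species (Na⁺, K⁺, Ca²⁺, Cl⁻, HCO₃⁻, CO₂) wash out to their
  pre-ischemic values with τ = 3.75×10⁴ ms (a few percent of the initial
  gap after two minutes); ATP and PCr recover toward 40 % and 75 % of
  their pre-ischemic concentrations (τ = 1.5 min); osmolarity relaxes on
  the washout time constant (its own constant is not separately stated).
  Intracellular pH is dynamic.

### The generic anion and charge bookkeeping

The imposed metabolic acidosis must be charge-neutral: each surplus
proton is paired with a generic monovalent anion.  Taken literally as an
algebraic function of pH at all times, that pairing would hide real
transmembrane proton transport from the charge sum (the NHE would look
electrogenic).  The anion is therefore integrated as the cumulative
*imposed* production during ischemia — the prescribed change in free plus
buffer-bound protons corrected for what the transporters and the
CO₂/bicarbonate equilibration actually moved — which reduces exactly to
the algebraic surplus when those pathways are silenced (a test asserts
this), while keeping every transporter electroneutral in the voltage.

During reperfusion the accumulated anion leaves together with a proton
as a neutral pair (τ = 12.5 min by default), representing lactate washout
and oxidative consumption.  This choice was forced by an observable
constraint: with realistic intrinsic buffering (~26 mM/pH) the roughly
30 mM of proton-equivalents accumulated during ischemia cannot be
removed in ten minutes by the NHE alone — and the experiment grid shows
substantial pH recovery even with the NHE fully blocked.  The neutral
co-export supplies exactly that NHE-independent recovery without
touching the sodium ledger or the charge balance.

## Numerical choices

* Forward Euler at Δt = 0.005 ms for every state (gates included; no
  exponential-integrator shortcut), matching the published single-method
  scheme; a step-halving test and an adaptive-step (lsoda) reference on
  short windows bound the integrator error.
* The purely voltage-dependent kinetics are tabulated on a 0.02 mV grid
  with linear interpolation inside the driver; the exact-evaluation path
  (used by the exposed rate functions and the reference integrator) is
  direct.  The interpolation error is orders of magnitude below the
  integrator error.
* Any concentration crossing zero aborts the run with the variable name,
  time and phase — never silently clamped, because clamping would break
  the conservation tests.  The anion tolerates −10⁻⁶ mM of roundoff.
* The sodium ledger is accumulated over every tenth step during
  reperfusion (the same decimation at which series data would be
  written), deliberately a rectangle sum over retained samples rather
  than the exact integral.
* Series output decimation is configurable; by default it targets about
  50,000 retained rows per run.

## Calibration against the initial state

Constants that the sources leave open are closed on the initial state
itself: the CHE and AE scales make pH and bicarbonate stationary at
t = 0; the background Cl⁻ conductance balances the chloride loaders; SR
leak balances SERCA uptake at the initial SR load; metabolic CO₂
production balances membrane CO₂ efflux; and the pump amplitude is the
initial sodium influx times a pacing reserve (the margin the pump needs
once 3-Hz pacing adds Na⁺ load).  The creatine-kinase and
adenylate-kinase equilibrium constants and the total creatine and
phosphate pools are closed from the initial phosphometabolite block, so
the dependent pools reproduce their stated values exactly at t = 0.

Constants with no printed value anywhere (K_ATP conductance, pump pH pK,
phosphate inhibition of the pump, water-flux coefficient, transporter
scales) were chosen once so that the *qualitative* end-ischemic phenotype
is right — extracellular K⁺ accumulation into the mid-teens, a strongly
depolarized resting potential, intermittent stimulus capture, continued
extracellular acidification beyond the intracellular clamp — and were not
revisited against the quantitative summary tables.

## Desk-scale (time-compressed) protocols

A full 5+20+10-min protocol integrates 4.2×10⁸ Euler steps.  For tests
and quick exploration the schedule supports *trajectory compression*:
phases are shortened while every prescribed trajectory and relaxation
advances `compress` trajectory-milliseconds per simulated millisecond, so
a 5-min compressed ischemia traverses the full severity of the imposed
insult.  Compression preserves the imposed conditions but shortens the
real time over which the free dynamics (sodium loading, pH recovery)
act, so absolute concentrations differ from the full-scale run; the
mechanistic orderings across intervention scenarios are what desk-scale
runs are used to check.  The acceptance suite runs the control and
R-series scenarios at full scale and the complete grid at desk scale,
sharing identical protocol prefixes across scenarios through exact
segment restarts.

## What the passing tests do and do not show

The property suite demonstrates internal consistency: conservation of
matter and charge, integrator convergence, exact anion bookkeeping, the
stated relaxation times, determinism and restartability.  The scenario
tests demonstrate the mechanistic signatures of the reconstruction —
pump-mediated paradoxical sodium overload under NHE inhibition, the
benefit of removing the pump's acidotic inhibition, potassium-driven
depolarization and capture failure.  They do not demonstrate agreement
with any particular animal preparation, and the quantitative summary
tables of the source parameterization are reproduced only approximately:
the component algebra here is reconstructed from the published model
family rather than transcribed from a single reference implementation,
and several sensitivity constants had to be chosen fresh.

## Known limitations

* No tension development, mitochondrial physiology, reactive oxygen
  species or apoptosis; the phosphometabolite schedules are a proxy for
  metabolic failure.
* Acidosis sensitivities of currents that the source parameterization
  deliberately omitted are omitted here as well.
* Single cell only; abrupt total ischemia only (graded protocols would
  need schedule changes).
* The ischemic late-Na scale is ambiguous in the source (an "increase"
  narrative beside a smaller printed number); both readings are
  available via `protocol_schedule(inal_ischemic = )`, defaulting to the
  increase reading (0.0018).
* The sign of the R-series *peak*-sodium ordering is a knife-edge: at
  the reperfusion sodium peak, the extra sodium the NHE carries in the
  uninhibited run and the extra pump impairment the inhibited runs
  suffer from their slower pH recovery nearly cancel.  In this
  reconstruction the direct NHE term wins by ~1–2 mM (control peak
  slightly above the full-block run); the source parameterization tips
  the other way by a similarly small margin.  The pH orderings and the
  mean-sodium ordering across the grid do not depend on this balance
  and are asserted by the acceptance suite; the peak ordering is
  asserted too and is an expected failure of the reconstruction.
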