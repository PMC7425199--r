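---
title: "The mouse atrial myocyte model: equations, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mouse atrial myocyte model: equations, calibration and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamyo)
```

## What the model is

`mamyo` is a deterministic ordinary-differential-equation model of a single
mouse atrial myocyte. The state vector has 55 components: the membrane
potential; Markov-chain occupancies for five gating schemes (7-state L-type
Ca^2+^ channel, 7-state transient-outward K^+^ channel, 6-state ultra-rapid
delayed rectifier, 5-state rapid delayed rectifier, 4-state ryanodine
receptor); six Hodgkin–Huxley gates (fast/late Na^+^ and the slow
steady-state K^+^ activation gate); bulk Na^+^, K^+^ and Cl^−^; free Ca^2+^
in four compartments (dyadic cleft, sub-sarcolemmal shell, bulk cytosol,
sarcoplasmic reticulum); eight explicit Ca^2+^ buffers; and a reduced
signalling layer (per-compartment active CaMKII fractions and the
phospholamban phosphorylation fraction). The original modelling lineage this
work descends from integrates a substantially larger system (the published
figure is 159 equations, most of them in a β-adrenergic receptor cascade
whose parameters are not in the main text); here that cascade is collapsed
to four static PKA phosphorylation fractions (`pka_ltcc`, `pka_plb`,
`pka_nak`, `pka_ryr`), which preserves the signalling interface without
inventing kinetics.

Units are fixed throughout: mV, ms, pA/pF, mM; Ca^2+^ fluxes are
cytosol-referenced mM/ms except the SR release flux, which is SR-referenced
and converted through the volume-fraction ratio. The membrane equation uses
the standard specific-capacitance normalization, so 1 pA/pF = 1 mV/ms.

## Markov gating

Each channel is a continuous-time Markov chain with generator `Q(V,
ligands, T)`: column sums vanish, so total occupancy is conserved, and all
states are integrated explicitly with renormalization only at beat
boundaries when drift exceeds 10^−9^. Key structural features:

* **L-type Ca^2+^ channel** — the C2↔C1 transition is strongly
  voltage-dependent with 4.4 mV added to the voltage inside its rates (the
  leftward shift of the steady-state activation); C1↔O is
  voltage-independent; two inactivation branches carry Ca^2+^-dependent
  (driven by cleft Ca^2+^, relieved by CaMKII) and voltage-dependent
  inactivation. Current flows by a Goldman–Hodgkin–Katz flux; the
  conductance is the parent-scale value times the printed 1/4 reduction.
* **Transient outward K^+^** — an activation ladder (C3→C2→C1→O with
  multiplicities 3α/2α/α) plus one fast and two slow inactivated states;
  kinetics are authored at 22 °C and rescaled with Q~10~ = 1.8 (kinetics)
  and 1.1 (conductance).
* **Ultra-rapid K^+^** — a 6-state ladder whose activation rates α and β
  carry an explicit ×1/8 factor (the printed slowing of activation), plus a
  slow inactivated state; Q~10~ = 1.9/1.37 from 22 °C.
* **Rapid delayed rectifier** — C3↔C2↔C1↔O↔I with fast voltage-dependent
  O↔I inactivation, which produces inward rectification during
  depolarization and a resurgent tail on return to −40 mV; fitted directly
  at body temperature, no Q~10~.
* **Ryanodine receptor** — R/O/I/RI gated by cleft Ca^2+^ with an
  SR-load-dependent sensitivity (EC~50~ = parent value × 0.9 inside the
  `kCaSR` term, so a fuller store opens more readily and inactivates less).

### The RyR opening law

The one place where this package departs structurally from its parent
framework is the Ca^2+^ dependence of RyR opening. A quadratic mass-action
opening rate, combined with a common-pool cleft, put the model on a knife
edge during calibration: depending on the release scale the system either
failed to ignite, locked into a self-sustaining leak state (elevated
standing cleft Ca^2+^ holding the channel open against a depleted store),
or alternated beat-to-beat. The shipped model instead uses a *saturating*
activation term with tetramer-like cooperativity,

\[ k_{open} = \frac{k_o}{k_{CaSR}} \cdot
   \frac{[Ca]_{cleft}^4}{[Ca]_{cleft}^4 + K_d^4}, \qquad K_d = 15\ \mu M ,\]

which separates diastolic cleft Ca^2+^ (~0.15 µM, opening rate ~10^−8^
ms^−1^) from the trigger excursion (tens of µM, opening rate ~0.5 ms^−1^)
by more than six orders of magnitude. Release then fires promptly on every
beat, terminates through Ca^2+^-dependent inactivation and store-load
feedback rather than store exhaustion, and is graded rather than
all-or-none. Recovery from inactivation (`kim` = 0.001 ms^−1^) gives the
release its refractoriness and suppresses the slow "trickle" release that
otherwise distorts the transient's decay. Caffeine is emulated as a ×7.5
multiplier on the Ca^2+^ seen by this activation gate — a sensitization,
which is also how caffeine acts on the receptor — together with full SERCA
and background-Ca^2+^ block; a plain rate multiplier cannot open the
saturating gate at diastolic Ca^2+^ and would make the caffeine protocol
inert.

## Calcium handling

SERCA follows the reversible parent form with the printed modifications
(V~max~ halved, forward affinity K~mf~ raised 13%) and the CaMKII scaling

\[ K_{SERCA} = \frac{1}{(0.0167/Ph_{PLB})^{12} + 1}, \qquad
   V_{max,eff} = V_{max}\,(1 + K_{SERCA}). \]

`Ph_PLB` is treated as a fraction (the midpoint constant 0.0167 is
dimensionless); the `1 + K` form makes the pump rate approximately double
once phospholamban phosphorylation crosses the midpoint, matching the
reported ~2× acceleration of SERCA turnover at 4 Hz versus 0.5 Hz, and
keeps the uptake flux strictly increasing in the factor. Phospholamban
phosphorylation follows cytosolic CaMKII with deliberately slow kinetics
(tens of seconds), so frequency-dependent acceleration of relaxation
develops over many beats.

Diffusion between cleft, shell and cytosol is linear in the concentration
gradients. The coefficients are scaled to this cell's compartment volumes
so that the cleft drains with a ~0.1 ms time constant (fast enough to kill
pathological standing gradients, slow enough that the L-type flux plus
early release build a tens-of-µM trigger) and the cytosol fills over a few
ms. Buffering is explicit (troponin, calmodulin, SR-membrane sites, two
sarcolemmal sites per shell compartment, calsequestrin in the SR), which
makes total-Ca^2+^ conservation with a closed sarcolemma an exactly
testable identity rather than an approximation.

## Membrane currents and ionic bookkeeping

Non-Markov currents follow standard formulations: m³hj fast Na^+^ current;
late Na^+^ current with the printed +68% conductance; an inward rectifier
derived from the usual two-rate rectification function with an added
rectification-strength parameter (`k1_rect`, see below); a single-Boltzmann
background K^+^ current fitted at 37 °C with no time constant; a
single-gate steady-state K^+^ current with conductance 0.049 nS/pF and
Q~10~ 2.4 applied to both its time constant and its conductance;
acetylcholine-gated and small-conductance Ca^2+^-activated K^+^ currents
(ACh = 0 at baseline, the Ca^2+^-activated K^+^ current included); Ca^2+^-
activated and background Cl^−^ currents; the Na^+^/K^+^ pump at 60% of the
parent maximal rate; the electrogenic 3:1 Na^+^/Ca^2+^ exchanger with
allosteric Ca^2+^ activation; and the sarcolemmal Ca^2+^ pump.

Every current is booked to its carried species, and the stimulus (square
pulse, 10 pA/pF inward, 4 ms — about 1.5× the model's ~7 pA/pF threshold)
is booked as a K^+^ flux, so at a paced steady state the net transmembrane
flux of each species integrates to zero over a cycle. One caveat is the
Cl^−^ pool: its currents are small by construction, so Cl^−^ equilibrates
over minutes of simulated time; per-cycle net/gross flux ratios are
meaningful for Na^+^, K^+^ and Ca^2+^ but not for Cl^−^, whose convergence
is instead bounded in absolute drift.

## Calibration: what was fitted, and to what

The published description of this cell model states its modifications to a
ventricular parent framework (the multipliers ×0.25 g~CaL~, ×1/8 α,β of the
ultra-rapid channel, ×1.68 g~NaL~, ×0.6 I~NaK~, ×0.5 V~max~, ×1.13 K~mf~,
×0.9 EC~50~, the −4.4 mV shift, the Q~10~ set, 0.049 nS/pF) but not the
underlying rate tables.
All rate coefficients here were therefore authored with the stated
structure and calibrated against the printed model outputs, in two stages:

1. **Channel level.** Each Markov channel was run under its published
   voltage-clamp protocol (matrix-exponential propagation, exact for
   piecewise-constant voltage) and its conductance/rate scales set so the
   printed densities are met: peak L-type density 4.76 pA/pF near 0 mV
   (hold −90 mV, 250-ms steps), 11.6 pA/pF at +30 mV for the transient
   outward current (hold −75 mV, 500-ms steps), 5.1 pA/pF at +30 mV for
   the ultra-rapid current (hold −80 mV), and 3.32 pA/pF at +30 mV for
   the steady-state current (hold −80 mV). The 0.049 nS/pF conductance is
   interpreted as the body-temperature value; its activation midpoint was
   the free coefficient.
2. **Cell level.** With channel densities pinned, the remaining free
   parameters (inward rectifier and background conductances, pump and
   exchanger scales, SERCA V~max~, release scale, diffusion, geometry)
   were tuned at the paced steady state to: APD at 90% repolarization
   ≈ 24.4 ms at 2 Hz; ≈ 2.6 ms APD~90~ prolongation under full rapid-
   delayed-rectifier block; diastolic cytosolic Ca^2+^ ≈ 0.11 µM and a
   ≈ 2.6-fold transient at 0.5 Hz; maximal upstroke velocity near
   210 V/s; excitation threshold near 7 pA/pF.

Two parameters were added to make stage 2 solvable at all.
`k1_rect` (< 1) weakens the inward rectifier's rectification at
depolarized potentials, supplying the outward current that drives the
fast final repolarization of the very short mouse atrial action potential
without raising the resting conductance in step. `na_mshift` shifts the
Na^+^ activation gate 11 mV leftward; without it the charge needed to
reach Na^+^-channel takeoff against the resting rectifier put the
excitation threshold near 9 pA/pF instead of the printed ~7 pA/pF. Both
are departures from "kinetics unchanged from the parent" and are the
package's own design choices.

Known deliberate misses, accepted during calibration: the resting membrane
potential sits near −84 mV (a few mV deeper than typical records); bulk
Na^+^ relaxes to ~13 mM rather than ~10.8 mM in quiescence; K^+^ depletion
at 10-Hz pacing is directionally correct but shallower than reported. These
trade against the quantities above, which were prioritized because they are
the printed validation numbers.

## Numerical choices

* Integrator: `deSolve::lsoda` driving a compiled-C right-hand side; an
  equation-identical reference implementation in R is kept and the two are
  compared at random states in the test suite (agreement ~10^−15^).
* Tolerances: rtol 10^−6^; atol 10^−9^ mM for free Ca^2+^ states, 10^−6^
  elsewhere. Halving tolerances moves APD~90~ by < 0.1 ms.
* Discontinuities: every stimulus edge and clamp step is an integration
  restart; output is sampled on a uniform grid (default 0.1 ms).
* Degenerate inputs: occupancies are renormalized when drift exceeds
  10^−9^; `Ph_PLB` is clamped at 10^−6^ inside the SERCA factor;
  the Goldman flux uses a series expansion near V = 0.
* APD convention: measured from the instant of maximal upstroke velocity
  (configurable to stimulus onset) to the linearly interpolated crossing of
  RMP + (1 − x/100)·APA, with the RMP and amplitude taken per beat.
* Transient decay: monoexponential least-squares fit from the peak to 10%
  above diastole.
* S1S2 capture: an S2 beat counts as evoked when its maximal upstroke
  velocity reaches 10 V/s; sub-threshold beats are flagged, not errors.
  Twenty S1 beats precede each S2 by default. Near the refractory floor the
  premature response shows a small supernormal bump before the restitution
  curve turns monotone.
* Steady-state pacing: the convergence contract is beat-to-beat relative
  change of APD~90~, end-diastolic Ca^2+^, Na^+^ and K^+^ all below 10^−4^
  (the source never defines one). Note that bulk Na^+^ equilibrates over
  hundreds of beats; analyses that need deep ionic steady state (e.g.
  per-cycle flux balance) should budget for that or start from the stored
  snapshots in `inst/extdata/`.

## Problem sizes used by the tests and scripts

The test suite warm-starts heavy simulations from two stored deeply
converged states (2 Hz and 0.5 Hz) and adds touch-up beats, keeping the
default run to about a minute. The acceptance script paces from the
package's resting state from scratch: roughly 1200 beats at 2 Hz for the
control and blocked action potentials and 400 beats at 0.5 Hz for the
Ca^2+^ transient, chosen so the slow Na^+^ drift has settled (beat-to-beat
Na^+^ change below 2·10^−5^ mM).

## What the synthetic fixtures do and do not show

The analytic fixtures (`fixtures()`) — a two-state channel with known open
fraction, a detailed-balance ring with Boltzmann weights, a triangular
action potential with geometric APDs, an exponential transient with a known
decay constant — validate the *machinery*: generator assembly, stationary
solvers, feature extraction, fitting. Passing them says nothing about
biological fidelity; that burden is carried by the calibration targets and
the directional properties (frequency-dependent acceleration of relaxation,
left/right atrial ordering, K^+^-clamp abolition of resting-potential rate
dependence, 12.5-Hz stability).

## Known limitations

Single common-pool dyad: no Ca^2+^ sparks or intracellular wave
propagation, so release is spatially uniform by construction. No
myofilament mechanics, no tissue coupling, no sinoatrial pacemaking. The
β-adrenergic cascade is a static phosphorylation interface, not a receptor
model. Drug block is a static conductance multiplier without
state-dependent binding. The left atrial variant rescales exactly two
conductances (ultra-rapid ×2.10, inward rectifier ×1.70); other measured
left/right density ratios are listed in the source of `make_variant()` but
not applied.
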