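# mamyo — a mouse atrial myocyte electrophysiology model

`mamyo` simulates the electrical action potential and intracellular
calcium handling of a single mouse atrial cardiomyocyte. It is aimed at
cardiac electrophysiologists and modellers who use the mouse as an
arrhythmia model and need a cellular substrate for in-silico
voltage-clamp, pacing, restitution and channel-block experiments.

## The model

The cell is a deterministic system of 55 ordinary differential equations:

* **Markov-chain ion channels.** The L-type Ca²⁺ current (7 states, with
  Ca²⁺- and voltage-dependent inactivation and a 4.4 mV leftward shift of
  the C2↔C1 activation step), the transient-outward K⁺ current *I*to
  (7 states), the ultra-rapid delayed rectifier *I*Kur (6 states, with
  activation rates at 1/8 of their parent values), the rapid delayed
  rectifier *I*Kr (5 states), and the ryanodine receptor (4 states, gated
  by dyadic-cleft Ca²⁺ with store-load-dependent sensitivity). Occupancies
  obey d**p**/dt = **Q**(V, ligands, T) **p** with a conservative
  generator **Q**; kinetics carry per-channel Q₁₀ factors (1.8/1.1 for
  *I*to, 1.9/1.37 for *I*Kur, 2.4 for the steady-state current).
* **HH and algebraic currents.** Fast and late Na⁺ currents, the
  non-inactivating steady-state K⁺ current (one activation gate,
  0.049 nS/pF), inward-rectifier, background and Ca²⁺-activated K⁺ and
  Cl⁻ currents, the Na⁺/K⁺ pump (maximal rate reduced 40%), the 3:1
  Na⁺/Ca²⁺ exchanger, and the sarcolemmal Ca²⁺ pump.
* **Four-compartment Ca²⁺ handling.** Dyadic cleft, sub-sarcolemmal
  shell, bulk cytosol and SR, with explicit buffers and SERCA uptake
  scaled by CaMKII through phospholamban phosphorylation:
  K_SERCA = 1 / ((0.0167 / Ph_PLB)¹² + 1), V_max,eff = V_max (1 + K_SERCA),
  which produces frequency-dependent acceleration of relaxation.
* **Left/right atrial variants.** The left-atrial cell is the right-atrial
  baseline with *I*Kur × 2.10 and *I*K1 × 1.70.

Stiff integration uses `deSolve` (lsoda) with a compiled right-hand side;
an equation-identical R implementation is kept as a tested reference.

## Worked example

Channel-level voltage clamp — the transient-outward K⁺ family (holding
−75 mV, 500-ms steps):

```r
library(mamyo)
p <- default_parameters()
fam <- run_voltage_clamp("Ito", standard_clamp_protocol("Ito"), p)
iv_summary(fam, "peak")
#>   V     I
#>   0  3.05
#>  10  6.31
#>  20  9.29
#>  30 11.60     # peak density 11.6 pA/pF at +30 mV
#>  40 13.41
#>  50 14.93
```

A steady 2-Hz action potential and its features (warm-started from the
shipped steady-state snapshot):

```r
y <- read_state(system.file("extdata", "steady_2hz_ra.json", package = "mamyo"))
beat <- integrate_model(y, p, pacing_protocol(cl = 500), t_span = 500, grid = 0.05)
round(ap_features(beat), 2)
#>    RMP     OS    APA dVdt_max APD20 APD30 APD50 APD90 APD50_APD90
#> -84.64  23.52 108.16   225.21  3.13  5.27 11.74 22.91        0.51
```

The resting potential sits near −85 mV, the upstroke reaches ~225 V/s and
the action potential is over within ~23 ms at 90% repolarization — the
short triangular morphology characteristic of mouse atrium. The 0.5-Hz
calcium transient and the partitioning of its removal:

```r
y5 <- read_state(system.file("extdata", "steady_05hz_ra.json", package = "mamyo"))
b5 <- integrate_model(y5, p, pacing_protocol(cl = 2000), t_span = 2000, grid = 0.1)
round(cat_features(b5), 3)
#> ca_dia ca_peak amp_ratio    ttp tau_decay
#>  0.105   0.283     2.704 13.700   154.253
round(ca_removal_partition(b5), 1)
#> SERCA   NCX  PMCA
#>  88.6   7.1   4.3
```

Diastolic cytosolic Ca²⁺ is ~0.10 µM, the transient peaks ~2.7-fold above
it, and SERCA dominates removal with the exchanger near 7% — the
SR-centred Ca²⁺ cycling expected of murine myocardium. Drug-block
experiments go through a closed registry, e.g.
`apply_block(p, drug_to_block("4-AP", "100uM"))` for 30% *I*to / 100%
*I*Kur block, and a thin command line (`inst/exec/mamyo`) exposes `pace`,
`vclamp`, `s1s2`, `caffeine`, `block`, `sweep`, `features` and `fixtures`
subcommands.

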