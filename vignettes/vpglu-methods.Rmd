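---
title: "Modelling depolarization block in glutamatergic ventral pallidum neurons"
author: "vpglu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling depolarization block in glutamatergic ventral pallidum neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific question

Glutamatergic neurons of the ventral pallidum (VP) fall into two
electrophysiological classes: cells that enter depolarization block (DB)
as current injections grow — their firing rate rises to a peak and then
collapses — and cells that keep firing across the tested range (NDB).
Parvalbumin (PV), a fast calcium buffer, is expressed in a subset of VP
neurons and is classically associated with fast-spiking, block-resistant
phenotypes. `vpglu` implements a population-of-models workflow to ask
whether PV expression can convert one firing phenotype into the other:
build a biophysical VP neuron model, calibrate *populations* of models
against the summary statistics of each experimental class, then titrate
a PV buffering mechanism across both populations and measure what it
does to the F-I curve, the ramp threshold and the phenotype labels.

## The cell model

The cell is a ball-and-stick morphology with a myelinated axon, an
unbranched chain of compartments:

* soma: cylinder, 10 µm × 10 µm, passive;
* axon hillock: 30 µm × 1 µm, carrying the eight active conductances;
* dendrite: a single equivalent cable, 1371 µm × 0.3 µm, passive — its
  length is what places the cell's input resistance in the
  experimentally observed gigaohm range;
* axon: 100 nodes of Ranvier alternating with 99 internodes (node
  first). Nodes carry the squid-type scheme at its stock densities
  (g_Na = 0.12, g_K = 0.036 S/cm²). Internodes are passive with a
  heavily myelinated capacitance of 0.005 µF/cm² and low leak
  (10⁻⁵ S/cm²): at thicker effective myelin (higher capacitance)
  conduction across the 100 µm internodes is decremental and the spike
  dies mid-axon, while raising nodal densities instead poisons the
  resting state (the axon's potassium rest conductance drags the
  resting potential toward E_K and halves the input resistance), so
  the thin-capacitance sheath is the one axon design that yields both
  end-to-end propagation and the observed gigaohm passive properties.

Passive constants not fixed by the experimental description are
declared defaults, not facts: membrane capacitance 1 µF/cm², axial
resistivity 150 Ω·cm, leak reversal −60 mV (matching the −60 mV
initialization so that rest ≈ init). All are config-exposed.

The free parameters are nine maximal conductances
(`conductance_names()`): Nav1.6, delayed-rectifier K, A-type K, SK, BK,
M-type K, L-type Ca, T-type Ca — expressed in the hillock only — plus a
passive leak applied uniformly to soma, dendrite and hillock.

### Channel kinetics are declared, auditable defaults

The experimental literature this model family draws on does not print
its channel equations, so every channel ships as a parameter table
(YAML, one file per channel under `inst/extdata/channels/`): Boltzmann
steady states with constant or bell-shaped time constants, gate
exponents and reversal potentials (E_Na +60, E_K −90, E_leak −60 mV;
calcium channels use a fixed ohmic E_Ca +120 mV approximation). The SK
gate is a Hill function of submembrane calcium (EC50 0.5 µM, Hill
coefficient 2 — an *effective* coupling for a 0.5 µm shell, see below);
the BK gate is a Boltzmann in voltage whose midpoint shifts −40 mV per
decade of calcium. Three choices deserve emphasis because the
phenotypes depend on them:

* **The sodium channel has a slow inactivation gate.** Nav1.6 is
  m³·h·s: besides the fast Boltzmann inactivation (h, midpoint −52 mV,
  τ up to ~20 ms), a slow gate s (midpoint −45 mV, τ = 250 ms) engages
  only when the membrane dwells above about −50 mV. During sustained
  strong steps the depolarized envelope erodes s over hundreds of
  milliseconds and firing collapses mid-step — use-dependent
  depolarization block whose onset time shortens smoothly with
  amplitude, which is what makes the DB population's F-I curves rise
  and then decline gradually rather than switching off. Slow
  subthreshold approaches (the 1-s ramp) are spared because the ramp's
  trajectory crosses the engagement zone quickly relative to τ_s; in
  low-sodium regimes the T-type window transient provides the ramp's
  first spike.
* **SK protects against block; the delayed rectifier inactivates
  slowly.** SK-driven afterhyperpolarizations pull the trough down
  after every spike, letting sodium channels recover; whether a
  parameter set is DB or NDB is largely set by the balance between
  injected current and the SK/delayed-rectifier repolarization
  reserve, which is exactly the dial PV buffering turns. The delayed
  rectifier additionally carries a slow (Kv2-like) inactivation gate
  (midpoint −40 mV, τ = 300 ms) that erodes it under sustained
  depolarized firing envelopes while leaving rest and ordinary
  interspike behaviour untouched.
* **Nodal kinetics are temperature-rescaled.** The squid-type nodal
  scheme is defined at 6.3 °C; it runs here with its native Q10 of 3
  rescaled to the 23 °C operating temperature (rate factor ≈ 6.3).
  Without this the axon's slow potassium gating dominates the somatic
  afterhyperpolarization and no depolarization-block regime exists
  anywhere in conductance space. The hillock tables are defined at
  23 °C directly; a global Q10 hook exists and defaults to 1.

### Calcium and the parvalbumin buffer

Each hillock compartment has a submembrane calcium shell: influx
proportional to the local calcium current, first-order extrusion to a
50 nM baseline with τ = 20 ms. The shell depth is 0.5 µm. This is a
deliberate deviation from the thinnest conventional shell (0.1 µm): at
0.1 µm a single spike's transient sits two orders of magnitude above
any physiologic SK EC50, so SK either saturates for ~100 ms per spike
or — if its EC50 is raised to compensate — decouples from subthreshold
calcium entirely, and the buffer experiment loses its observable. At
0.5 µm, spike transients land at roughly 2–10× the SK EC50 and
subthreshold (T-type window) calcium sits on the rising limb of the SK
activation curve, so both spike-triggered AHPs and subthreshold
braking are live, buffer-sensitive mechanisms.

Parvalbumin binds calcium by mass action
(d[CaPV]/dt = k_on·[Ca]·([PV]−[CaPV]) − k_off·[CaPV];
k_on = 40 mM⁻¹ms⁻¹, k_off = 4×10⁻⁴ ms⁻¹, i.e. Kd = 10 nM), with no
magnesium competition. Calcium and buffer advance together by an
implicit 2×2 Newton step, which conserves calcium to machine precision
and reduces *exactly* to the unbuffered update at zero total PV — so a
0 mM titration level reproduces baseline metrics bit for bit. At
stimulus onset the buffer starts equilibrated to baseline calcium
(bound fraction Ca/(Ca+Kd)), avoiding an artificial onset transient;
"concentration" everywhere means total PV.

## Numerics

The cable equation is integrated by backward Euler at dt = 25 µs on the
compartment chain (the tree is unbranched, so the implicit system is
tridiagonal and solved exactly by the Thomas algorithm each step).
Membrane currents are linearized about the current gate values within a
step; gates then relax by their exact exponential update at the freshly
solved voltage (operator splitting), with rate lookup tables on a
0.05 mV grid. The scheme is unconditionally stable at 25 µs; the test
suite checks that spike counts on the full F-I grid are identical at
dt = 25 and 12.5 µs for the reference model, and that the all-passive
cell matches the closed-form sealed-end cable solution within 1%.
Simulations begin from the steady-state gate values at −60 mV and run
500 ms of equilibration before any stimulus; the equilibrated state is
computed once per parameter set and shared across all protocols (the
protocols are independent continuations of the same state, so this is
exact, not an approximation). A trace is declared divergent when any
compartment leaves ±200 mV; divergent parameter sets score +∞.

Spatial resolution: soma 1 segment, hillock 3, dendrite 41, nodes and
internodes 1 each. A mesh-refinement test (doubling every segment
count changes the passive input resistance by <0.5%) guards the
choice.

## Validation metrics and scoring

For each parameter set the full current-clamp battery runs: a −5 pA ×
500 ms input-resistance probe (mean of the final 50 ms minus
baseline), the 0–130 pA F-I grid in 10 pA steps (500 ms pulses; spikes
are local maxima above 0 mV with a −20 mV re-crossing debounce, so
plateau oscillations during block do not count), a 0→150 pA 1-s ramp
(threshold = instantaneous current at the first spike), and the
derived summary metrics (peak firing current with ties to the lowest
amplitude, rheobase, AHP at rheobase with the spike threshold defined
by dV/dt first exceeding 10 mV/ms).

Phenotype classification is operational: with r_max the peak rate and
r_end the rate at the final amplitude, NDB means r_end ≥ 0.8·r_max, DB
means r_end < 0.5·r_max with the peak before the end, nonspiking means
no spikes anywhere; in-between curves are indeterminate and treated as
DB-leaning. The thresholds are config-exposed; the tests assert
classification *stability* (re-simulation reproduces the label), not
the thresholds themselves.

The score of a parameter set against a target bundle is the mean of
four normalized distances: input resistance, ramp threshold (targeted
at the printed rheobase mean), peak firing current, and the F-I error
(sum of absolute rate differences over the grid divided by
14 × 5 Hz). Scalar metrics are normalized by the magnitude of the
target mean. SD normalization was considered and rejected: the printed
DB input-resistance dispersion (±15.8 MΩ on 1448 MΩ) is so tight that
no model population — including, by its own printed statistics, the
one this workflow is patterned on — could assemble under it;
normalizing "distance to the mean" by the mean keeps all four terms on
a comparable dimensionless scale. The SDs are still carried in every
bundle and are used by the recovery tolerances.

## Target bundles

`builtin_targets()` packages the printed patch-clamp statistics of the
two classes (peak firing current 122.2 ± 5.2 / 53.18 ± 6.5 pA, peak
rate 48.89 ± 7.6 / 20.76 ± 2.9 Hz, rheobase 25.32 ± 4.9 / 26.26 ± 4.7
pA, input resistance 1124 ± 239 / 1448 ± 15.8 MΩ for NDB / DB; AHP and
RMP are carried for reporting only). The population mean F-I curve is
published only as a figure, so the bundle carries a parametric curve
pinned to those statistics — zero below the rheobase mean, a concave
rise (exponent 0.8) to the peak rate at the peak firing current, flat
(NDB) or decaying to a quarter of peak (DB) beyond — and is tagged
`"paper-constrained surrogate"` so nobody mistakes it for printed
data.

`generate_surrogate_targets()` draws synthetic bundles of either
phenotype around configurable anchors (seed-reproducible), and
`ground_truth_fixture()` freezes the exact simulated metrics of one
parameter set as a target (SD = 10% of each mean, floor one unit) for
parameter-recovery testing — recovery is asserted at the metric level
only, because conductances themselves are not identifiable from these
protocols.

## Calibration

The sampler is Goodman–Weare affine-invariant ensemble MCMC (stretch
move, a = 2, red–black half-updates), written in R and verified
against analytic targets: moment recovery on a 2-D Gaussian, the
closed-form mean of the 1/√z scale density, affine invariance of
acceptance rates, and 50/50 occupancy of a symmetric two-point target.
The log-probability is −score/T with T = 0.05 (a Boltzmann shape; the
acceptance checks use metric recovery, not posterior shape, so they do
not depend on T). Uniform priors are constrained to per-channel
physiologic ranges (see `prior_spec()`); a flat 1 S/cm² bound on every
channel class was rejected because it concentrates the box in regimes
where calcium conductances saturate the shell and potassium window
currents latch the membrane at E_K.

The full configuration mirrors the published search: 10 independent
runs × 400 walkers × 25 iterations, run r initializing walkers at a
base guess plus Gaussian noise with standard deviation 0.05·r times
the prior box width, clipped into the box. The default base guess is
the package's reference conductance set (`reference_theta()`) rather
than the centre of the prior box: the centre of the physiologic box is
nonspiking, which would make every initial walker infeasible. The
reference set is a hand-validated NDB regime; the growing noise
schedule still carries later runs far from it.

`assemble_population()` collects every evaluated position with score
at or below the threshold, deduplicates within 10⁻⁹ relative
tolerance, re-simulates every survivor from scratch (nothing is cached
from the search), and keeps those whose re-simulated score still
passes and whose phenotype matches the target.

The default threshold of 0.5 mean-normalized units (an average metric
error of half a target mean) admits both phenotypes under the default
kinetics: hand-validated NDB regimes score around 0.3–0.45 and DB
regimes around 0.3–0.6. The published selection rule is unstated; the
threshold is config-exposed and every population records its members'
scores.

### Problem sizes

The paper-scale configuration is hours of CPU. The package's own test
and reproduction runs use reduced ensembles, chosen as the package's
standard verification sizes: the test suite calibrates at roughly
16–20 walkers × 6–8 iterations × 1 run against the builtin and
ground-truth bundles, and `scripts/acceptance.R` uses a comparable
scale; simulation-heavy unit tests use a shortened axon (21 nodes) and
coarser dendrite that preserve every electrical feature at about a
quarter of the cost. Population sizes at these scales are tens of
models rather than the published hundreds; the direction-of-effect
conclusions are asserted at these sizes, absolute population counts
are not.

## The PV experiment

`titrate_pv()` re-simulates every population member through the full
battery at total PV concentrations {0, 1, 2, 5, 10} mM (0 is the
stored baseline) and summarizes each level (mean ± SD of peak firing
current, peak rate, ramp threshold; pointwise mean F-I curve; DB
fraction). `titration_tests()` compares baseline against each
concentration per metric with a Mann–Whitney U test (midranks; exact
enumeration for pooled n ≤ 20, tie-corrected normal approximation with
continuity correction otherwise; U = min(U₁,U₂) reported with both
persisted). Comparisons are per-metric and uncorrected by default,
mirroring the per-star presentation of the source experiment; a
`p_adjust` flag exists. Unpaired tests are used, as the figure legends
state, although members are in fact paired across concentrations.

The mechanistic expectations, asserted as directions rather than
magnitudes: buffering attenuates spike-evoked calcium transients,
weakens SK activation, shifts the F-I curve leftward (more excitable
at low drive; for DB curves the whole rise-and-fall moves left, so
rates just below the unbuffered peak drop while the rising limb
gains), lowers the ramp threshold with saturation above 1 mM, and
never converts DB populations to NDB.

One published direction does **not** reproduce here, and the analysis
is worth stating plainly. Pushing NDB populations into depolarization
block at high PV requires the members to be *SK-paced*: cells whose
firing is rate-limited by the SK afterhyperpolarization, so that
buffering calcium removes both the brake and the block protection. In
this model family SK-paced NDB regimes cap near 26 Hz peak rate —
almost exactly where the original model population sat (25.3 ± 4.6 Hz,
a population its authors describe as under-excitable relative to the
recorded cells) — and score about 0.8 against the experimental
targets. Members that actually reach the experimental 48.9 Hz peak
rate, which the calibration selects (scores 0.3–0.5), are repolarized
by the delayed rectifier and the non-inactivating nodal axon; 5 mM PV
accelerates them past 200 Hz instead of blocking them (none of 50
calibrated members converted). The NDB-to-DB conversion at
supraphysiological PV is therefore a property of the original,
less-excitable model population, not of an experiment-rate-matched
one; the corresponding acceptance check is left failing with this
explanation rather than weakened.

## Known limitations

* Channel kinetics are plausible, auditable defaults, not the
  unpublished originals; absolute rates, the exact block current and
  population counts therefore differ from the published figures, and
  the package asserts reproduction only of directions and of
  statistics that the calibration itself constrains.
* The dendrite is a single cable; real VP neurons arborize, which
  raises input impedance further and adds dendritic calcium sources
  the model lacks.
* Active conductances live only in the hillock (plus nodal HH); somatic
  and dendritic active currents are absent by design, as in the
  modelling framework this follows.
* PV binding to magnesium is not modelled; with Kd = 10 nM and no
  competition the buffer is a stronger calcium sink than in vivo, so
  concentration thresholds should be read as model units, not
  physiological ones.
* The synthetic targets emulate population summary statistics, not
  cell-to-cell covariance; passing recovery tests shows the search can
  match mean behaviour, not that it reproduces biological variability.
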