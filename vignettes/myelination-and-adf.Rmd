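---
title: "Myelination and the spatial reach of analog-digital facilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelination and the spatial reach of analog-digital facilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Analog-digital facilitation (ADF) is the modulation of spike-evoked synaptic
transmission by the *subthreshold* membrane potential of the presynaptic
neuron. In cortical pyramidal cells two forms are established:

* **d-ADF** — a long (seconds) somatic depolarization spreads passively into
  the axon, inactivates the slowly gating axonal Kv1 (D-type) current
  (inactivation time constant ~1,500 ms), broadens the presynaptic spike,
  increases spike-evoked Ca^2+^ entry, and so enhances release.
* **h-ADF** — a brief (~200 ms) hyperpolarization lets axonal Nav1.6 recover
  from inactivation, enlarges the presynaptic spike, and likewise enhances
  release. Kv1 inactivation is untouched on this timescale, which makes
  h-ADF an amplitude-led phenomenon.

Both require the somatic voltage excursion to *reach* the bouton, so their
spatial reach is bounded by the axonal space constant. `adfsim` implements a
multicompartment layer-5 pyramidal-cell model to ask how myelination — wrap
number and internode length — changes that reach.

## The model

### Morphology

The cell is a soma (35 x 23 um), an axon hillock (10 x 2 um), an AIS
(50 x 1.2 um), a 20 mm main axon of 1.14 um diameter and ten 0.23 um
collaterals branching at 128.5, 129.6, 300.9, 301.5, 810.1, 993.9, 1,907.4,
2,922.4, 3,937.4 and 4,952.4 um of axonal path distance from the soma.
Presynaptic sites sit every 8 um along the collaterals; with the default
collateral lengths (1,980 um proximal, 1,000 um distal) the model holds
exactly 1,982 sites. The original reconstruction's dendritic tree is
replaced by an equivalent cylinder whose diameter is calibrated so that a
steady +322 pA somatic injection depolarizes the soma by exactly 15 mV
(`calibrate_dendritic_load()`); this preserves the somatic input resistance
that defines the study's operating points without requiring the
reconstruction itself. The proximal collaterals' lengths are not published;
1,980 um (vs the stated 1,000 um of the distal ones) is the choice that
honors the published total of 1,982 sites. What the surrogate deliberately
does *not* emulate: the branched sub-trees of real collaterals (relevant
only for site-count statistics, see Limitations), 3-D tortuosity, spines.

The main axon is segmented by `layout_internodes()`: a 1.5 um node of
Ranvier at every branch point (merging nodes of branch points closer than a
node), interior nodes splitting long stretches so internode lengths land
near the 100 um target (realized mean 101.3 um, range ~68-182 um; halving
or quartering the target gives means of 50.7 and 25.2 um) — branch-point
positions never move across layouts.

### Membrane and myelin

Channel densities follow the published tables: fixed somatodendritic
densities (Nav1.2, Kdr, leak; AIS Nav1.2 3,072->0 and Nav1.6 128->1,920
pS/um^2 as linear ramps) and nine axonal presets (`preset_names()`), from a
uniform non-myelinated axon (Nav1.6 370, Kv1 26.8 pS/um^2) through
myelinated variants with 2-20 wraps and 25-100 um internodes, plus a hybrid
axon with node-like hot spots but no sheath. Sheathed internodes carry only
leak. Reversals: E~Na~ +60, E~K~ -90, E~Ca~ +140 mV; R~i~ 150 Ohm cm;
C~m~ 1 uF/cm^2; 37 C.

Myelin geometry is a closed form: g-ratio 0.698 and a 0.57 um axon radius
give a 0.234 um sheath, i.e. 15.6 wraps of two 7.5 nm membranes; the main
model applies n = 15. A sheath of n wraps is an RC layer with
G~my~ = G~ax~/(2n) and C~my~ = C~ax~/(2n). Electrically each internode is a
double cable: the axolemma RC in series with a periaxonal space (12.3 nm
annulus of 53.7 Ohm cm fluid, axially conductive) beneath the sheath RC to
ground.

**Periaxonal end condition.** The periaxonal ends are *sealed* by default:
the space communicates with ground only through the sheath. The alternative
reading — periaxonal space continuous with the grounded extracellular medium
at the flanking nodes — is available (`periaxonal_ends = "grounded"`) but is
not the default for a quantitative reason: with the stated periaxonal
resistivity, a node-grounded annulus has an end-to-end resistance (~1.2
GOhm per 100 um internode) far below the sheath resistance, so at DC it
shunts the myelin entirely; the internode then insulates no better than
bare leak membrane, capping the myelinated/unmyelinated length-constant
ratio near 1.6 and eliminating the slow internode relaxation (~0.3 s with
sealed ends) that makes the 200 ms hyperpolarization measurably
non-stationary. Both the ~3-fold length-constant gain and the
hyperpolarization/depolarization asymmetry of the study require the sealed
(paranodally isolated) reading.

### Channel kinetics and their calibration

The study prints densities, not rate equations. `default_kinetics()`
therefore stores explicit, swappable parameter sets in the standard forms of
the L5 axon model family (trap-rate Nav m^3 h and Kdr n, Boltzmann Kv1 m h
with a fixed 1,500 ms inactivation time constant, Boltzmann m^2 P/Q Ca;
Q10 2.3 for the trap-rate channels). The free constants were fixed against
the study's own printed anchors, in this order:

1. *Resting balance.* With the tabled densities, the axonal leak reversal
   that holds rest at -70 mV must come out near the tabled -38.3 mV; this
   pins the resting Kv1 open fraction (~0.021) and bounds the resting
   persistent Na current. The package computes E_leak per region in closed
   form (`calibrate_preset_eleaks()`) and lands at -38.5 mV.
2. *Subthreshold attenuation.* The unmyelinated depolarization and
   hyperpolarization space constants (303.4 / 294.2 um) pin the Kv1
   activation midpoint and slope (-51.2 mV, k = 6).
3. *Spike modulation.* The first-site modulation chain (spike-area and Ca
   increases under depolarization; overshoot and Ca increases under
   hyperpolarization) pins Kv1 inactivation (midpoint at rest, -70 mV,
   k = 9), the Nav1.6 availability slope (k = 12), and the Ca activation
   curve (V~1/2~ +15 mV, k = 12, tau 0.3-0.6 ms).

Parameter regions that produced qualitative pathologies were excluded on
mechanistic grounds: Nav activation left of -37 mV makes the -55 mV
conditioning point bistable (the cell cannot be held subthreshold),
availability slopes flatter than k ~ 15 leave a window current that
plateaus the axon after a spike, and Kv1 inactivation midpoints below -72 mV
strip the conditioned spike of its repolarization reserve.

## Numerics

`discretize()` cuts sections into compartments (defaults: 25 um internodes,
single-compartment nodes, one compartment per 8 um site spacing on
collaterals so every site is a compartment center) and assembles axial
conductances. The stepper (`run_sim()`, compiled) advances the voltage
system with backward Euler and exact Hines elimination over the tree; gating
variables relax exponentially toward their steady state at the pre-step
voltage; the sheathed-internode layer is eliminated locally per step (its
coefficients are constant because sheathed axolemma is passive), except for
the small periaxonal axial current, which is explicit and bounds the step
(`run_sim` enforces dt below ~0.8x the periaxonal relaxation time; 6.25 us
spike steps are far inside the bound). Halving the 6.25 us spike step moves
the AP peak by ~0.2%; halving all compartment lengths moves the steady
somatic response by ~0.02 mV and the facilitation curves by <0.3 percentage
points.

Long subthreshold phases use `steady_state()`: gates held at their local
steady state and the nonlinear DC system solved by damped Newton with
pseudo-transient continuation (the persistent-Na region defeats plain
fixed-point iteration); it refuses, pointing to the time-domain path, when
no stable subthreshold solution exists. The 10 s depolarizing conditioning
is computed this way (every state variable has settled by 10 s: Kv1
inactivation tau 1.5 s, sheathed-internode relaxation ~0.3 s); the 200 ms
hyperpolarization is integrated in the time domain at 50 us steps because
it is genuinely non-stationary.

Conditioning is defined by its somatic operating point (+/-15 mV, i.e. -55
and -85 mV): +322 pA realizes +15 mV in the reference cell by construction
of the dendritic load, while the hyperpolarizing current is calibrated per
model starting from the published -344 pA (with the package kinetics that
current overshoots to about -86 mV; the published value reflects a
subthreshold rectification of the original's unpublished kinetics).

## The pipeline and its statistics

`run_experiment(preset, protocol)` runs the rest-spike control and the
conditioned protocol (3 nA / 3 ms trigger riding on the conditioning
current), measures the voltage-change profile at the soma and every main-
axon node, per-node spike metrics (`spike_metrics()`: overshoot above 0 mV,
amplitude above the local baseline, half-width, and the spike area above the
common -70 mV reference over the contiguous interval above a -20 mV gate,
so rest and conditioned areas share one reference), per-site spike-evoked Ca
charge (`ca_charge()` over a fixed window around each site's spike peak with
a linear pre-spike baseline removed — a whole-window constant-baseline
integral is contaminated by standing-current differences between
conditioning states), synaptic weights W = A Q^2.5, and EPSPs on a passive
postsynaptic compartment (alpha synapse, tau 1 ms, reversal 0 mV, R~in~ 100
MOhm, tau~m~ 20 ms; A is set so the control EPSP at the most proximal site
is 1 mV — none of these are published and only ratios matter, which the
test suite verifies are insensitive to A in the linear regime).

Statistics follow the study's definitions:

* `space_constant()` — the 37% rule: the linearly interpolated distance at
  which a profile falls to 37% of its origin value (5.55 mV for a 15 mV
  depolarization). Profiles that rise anywhere by more than 0.5% of the
  origin are *refused* as biphasic (the myelinated spike-area profile is
  the canonical case); profiles never reaching 37% are flagged, not
  extrapolated. Spike-shape profiles start at the first node of Ranvier
  (the measurement locations); subthreshold profiles start at the soma.
* `adf_spatial_extent()` — the last downward crossing of 105% on the
  facilitation curve sampled at the first site of each collateral.
* `site_fraction_ge()` — fraction of all 1,982 sites with >=5%
  facilitation, with the mean +/- SD distance of qualifying sites.
* `fit_wraps_curve()` — least-squares fit of sp(N) = a + b(1 - e^(-cN)) to
  the space constants across wrap counts (`sweep_wraps()`).

## What the default model reproduces

All quantities below are computed by the test suite and
`scripts/acceptance.R` at run time; representative values from the default
configuration: unmyelinated depolarization space constant ~295 um vs 303.4
reported (hyperpolarization ~315 vs 294.2); myelinated ~872 vs 906.6 and
~896 vs 858.5 — a 2.96x / 2.85x myelination gain vs the reported 2.99x /
2.92x; d-ADF extents ~810 um (unmyelinated, vs 836) and ~2,900 um
(myelinated, vs 3,124); first-site d-ADF ~144% of control vs 136.8%; the
space constant grows strictly with wrap number over {0, 2, 5, 10, 15, 20}
(fitted a ~ 308, b ~ 579 vs the reported 313.24 + 636.2(1 - e^(-0.189 N)))
and shrinks mildly as internodes shorten; the hybrid axon tracks the
unmyelinated one within a few percent on every space constant, isolating
the sheath, not the nodal hot spots, as the cause.

## Known limitations

* **Myelinated h-ADF extent.** The model's h-ADF reach in the myelinated
  axon (~3,770 um) overshoots the reported 2,894 um by ~30%: its distal
  hyperpolarization sensitivity (Q gain per mV at ~1 mV excursions) is
  about 1.7x the reported value while its proximal h-ADF saturates at the
  deep -15 mV operating point. This concavity is structural in the adopted
  kinetics family (the Na availability slope at rest plus
  hyperpolarization-improved collateral invasion) and is mesh-converged;
  matching it would require channel models beyond what the study prints.
* **Myelinated proximal d-ADF.** With a ~880 um space constant the first
  two collaterals sit at ~13 mV conditioning depolarization, where the
  modulation chain saturates: d-ADF rises from ~108% at 132 um to ~140% at
  814 um before decaying. The monotone-decay property therefore holds for
  the unmyelinated and hybrid axons but not the myelinated ones.
* **Spike half-width under h-ADF.** The study reports the hyperpolarized
  spike unchanged in duration (<1%); here its half-width shifts by up to
  ~12% because the axonal repolarization is Na-inactivation-dominated.
  h-ADF remains amplitude-led.
* **Site fractions.** The fraction of facilitated sites (reported 31.4%
  d-ADF unmyelinated) depends on the reconstruction's branched collateral
  trees, which concentrate many sites at short path distances; unbranched
  synthetic collaterals honoring the 1,982-site and branch-distance
  invariants cannot reproduce it. Fractions are computed and reported but
  not compared.
* Single deterministic cell; no channel noise, vesicle-pool dynamics,
  multi-spike trains, ion accumulation or temperature sweeps.

## Problem sizes and runtime choices

The default model has ~3,200 compartments (full 20 mm axon, all 1,982
sites). A complete experiment (control + conditioned runs, 40 ms spike
windows at 6.25 us, all-site analysis) takes tens of seconds; the
steady-state solves behind the space-constant sweeps take ~1 s each. The
solver-validation tests use reduced morphologies (4 mm axons, two
collaterals) — chosen as the smallest geometries that leave the proximal
attenuation and spike initiation unchanged.
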