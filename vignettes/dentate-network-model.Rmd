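---
title: "The dentatenet network model: biophysics, wiring, and analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dentatenet network model: biophysics, wiring, and analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dentatenet` simulates the principal local circuits of the rat dentate
gyrus — granule cells (GC) driven by the perforant path from medial and
lateral entorhinal cortex (MEC/LEC), basket-cell (BC) feedforward and
feedback inhibition, and the mossy-cell (MC) associational loop — at a
configurable fraction of full anatomical scale, together with the
population analytics needed to characterise the emergent activity:
distance-binned spatio-temporal spike correlations (STC), spike-density
spectra, and inter-spike-interval histograms.

This vignette is the package's account of its modelling choices: the
equations, the parameters that matter and their defaults, what the
generator does and does not emulate, and the numerical decisions.

## Populations and geometry

The full-scale model holds one million granule cells, 112,000 entorhinal
layer-II axons (split evenly between MEC and LEC), 6,000 basket cells and
30,000 mossy cells on a 10 mm septo-temporal axis. The mossy-cell count is
not fixed by the anatomical sources used for the other populations; 30,000
follows standard rat stereology and is configurable. Cells are placed
i.i.d. uniformly along the axis (density statistics are all that matter
downstream; no lattice structure is assumed) plus a normalised transverse
coordinate that only enters within-dentate conduction distances.

Reduced scales keep *all per-cell convergence values* and shrink only the
cell counts, so each neuron sees the same number of synapses as at full
scale. The package's default working scale is the 1:100 "desk scale"
(10,000 GC / 1,120 EC / 60 BC / 300 MC). Two consequences of this scaling
strategy are worth keeping in mind when interpreting reduced-scale runs:
presynaptic partners are drawn with replacement from fewer candidates, so
multiple synapses per pair make the afferent drive lumpier (larger
compound PSPs, higher per-cell rate fluctuations) than at full scale; and
population counts per spatial bin are smaller, so all spatial statistics
are noisier. Emergent regime structure (cluster formation, rhythm onset,
gain control) is preserved; absolute spike totals are not comparable
across scales.

## Cell models

### Granule cells

Granule cells use a reduced laminar scheme: a compartment chain
soma → granule-cell-layer segment (GCL) → inner → middle → outer
molecular-layer third, optionally multiplied into parallel equivalent
dendritic branches (default one branch, five compartments — parallel
identical branches are electrically equivalent for laminarly targeted
input). Each region carries the tabulated channel densities (S/cm²) for
transient Na, slow and fast delayed-rectifier K, A-type K (somatic only),
L-, N- and T-type Ca, SK and BK, with Na absent from the outer third, plus
region-specific leak and membrane capacitance (9.8 µF/cm² somatic/GCL,
15.68 µF/cm² dendritic thirds).

Compartment areas are not free parameters: given the region leak
densities, a dendritic/somatic area ratio (default 10) and an electrotonic
compactness factor (axial conductance = 10 × total membrane conductance),
the areas are solved so the somatic DC input resistance of the
five-compartment ladder equals the tabulated 185.86 MΩ exactly. The
printed somatic surface area is inconsistent with that input resistance
(4.97E-4 cm² of 2.9E-4 S/cm² leak alone gives ~7 MΩ), so the package
treats Rin, not the printed area, as binding. The measured membrane time
constant of the resulting cell is ~34 ms (tabulated: 31 ms, within the
model's ±15% acceptance band); it is bounded below 34.3 ms by the
region leak/capacitance ratios, which are fixed by the table.

Each compartment's leak reversal is solved so that the net membrane
current is zero at the tabulated resting potential with all gates at
steady state ("rest balancing", the standard practice in compartmental
modelling); the cells therefore rest exactly at −75.01 mV (GC) and
−64.75 mV (MC).

### Basket and mossy cells

Both are single-compartment somata. The mossy cell uses the tabulated
parameters (2.51E-3 cm², 0.6 µF/cm², 1.1E-5 S/cm² leak, Na 0.12,
KDR 5E-4, KA, L/N-type Ca, SK, BK). The basket cell block is not part of
the transcribed table; the package uses a fast-spiking single compartment
(1.4E-5 cm², 1 µF/cm², 5E-4 S/cm² leak → τ ≈ 2 ms, Rin ≈ 143 MΩ) with
transient Na and fast delayed-rectifier K.

### Channel kinetics

The biophysical sources print conductance densities only; gating kinetics
are the package's own, held in one swappable file (`R/kinetics.R`):
Traub-lineage rate functions for Na and the delayed rectifiers (the slow
rectifier is the fast one at 0.2 × rates), sigmoidal steady states with
fixed time constants for A-type K and the Ca channels, a Hill function of
intracellular Ca for SK, and a Ca- and voltage-dependent open fraction for
BK. Three calibrations deserve note:

* **Na inactivation closure.** With the very large tabulated Na densities
  (mossy cell Na:KDR density ratio 240:1), the classical 18 mV e-fold tail
  of Traub's α_h leaves a Na window current that supports a stable
  depolarisation-block plateau near −13 mV. Principal cells therefore
  close inactivation at 6 mV e-fold; the fast-spiking basket cell keeps
  the shallow 18 mV tail so it keeps firing under strong sustained drive,
  which is the fast-spiking phenotype.
* **Spike thresholds.** The threshold shift `vt` puts granule-cell spike
  onset at ≈ −47 mV (physiological for granule cells; the default −57 was
  chosen so the desk-scale granule population is excitable enough to
  sustain collective dynamics) and the basket-cell threshold high enough
  (−42 mV onset) that basket firing is phasic — driven by granule-cell
  population events — rather than tonic on the entorhinal background
  noise. Tonic basket firing flattens all cluster structure and precludes
  feedback rhythmogenesis.
* **Ca pool gain.** Each Ca-carrying compartment has a pool with 10 ms
  decay to the 5E-6 steady state; the influx gain (per unit area) sets
  spike-frequency adaptation. The mossy cell uses a 10× lower gain than
  the granule cell so it can sustain the burst firing this cell type shows
  in vivo instead of silencing itself through SK/BK after each event.

## Synapses and weights

Synaptic conductances follow the difference-of-two-exponentials
`g(t) = w·N·(e^(−t/τ_fall) − e^(−t/τ_rise))`, peak-normalised so
`max g = w`, with the tabulated rise/fall times per pathway (AMPA-like
throughout; the basket-to-granule synapse is GABA_A-like with E_rev
−75 mV; NMDA and GABA_B are deliberately absent). Kinetics rows that the
source table does not list (the mossy-cell pathways) default to the
perforant-path values 1.05/5.75 ms.

**Units.** The pathway weight table does not state units. The package's
default reads the weights as peak conductance *densities* (S/cm²) applied
to the target compartment — the same convention as every other
conductance in the biophysical table. The alternative reading (absolute
µS) renders the associational system inert: a 36 MΩ mossy cell can never
be brought to threshold by 20 pS unitary granule inputs at any plausible
convergence, which contradicts the reported behaviour of the network
(mossy bursts driven with ease by granule activity). Under the density
convention the granule-to-mossy synapse is a giant (~50 nS) terminal and
single granule spikes depolarise a mossy cell by ~10 mV, matching the
described physiology. `dg_network(weight_units = "uS")` restores the
literal reading.

One further calibration sits on top of the density convention: the
basket-to-granule weight carries a ×4 factor
(`dg_pathways(bc_gc_calibration = )`). The granule soma is the smallest
target compartment in the model, so the density conversion yields ~16 pS
per perisomatic contact — well below unitary GABA_A contact estimates
(~100 pS) — and with contacts that weak, feedback inhibition cannot
terminate granule population storms. The calibration restores a
physiological per-contact conductance; it parallels the original
modelling workflow, in which synaptic weights were adjusted to match
recorded PSP magnitudes.

Events are queued per synapse "slot" (one rise/fall state pair per target
compartment and kinetics class), so cost per step is O(slots), not
O(events); delayed deliveries add the pathway weight to both states.

## Topographic wiring

Connection probability is governed by Gaussian axon terminal-field
densities along the septo-temporal axis:

* **Entorhinal fields** are centred on the topographically mapped dentate
  coordinate (the tracer-derived zonal map is reduced to a 1:1 band map
  onto the axis) with a 1–1.5 mm reach (default extent 1.25 mm, σ =
  extent/2). MEC targets the middle third, LEC the outer third, both also
  the basket cells; fields span the whole transverse extent.
* **Local fields** (granule → hilus, basket → granule-cell layer) use a
  1 mm extent, σ = extent/2.
* **Mossy-cell fields** have an explicit position-dependent full span —
  2/3 of the axis for septal somata shrinking linearly to 1/3 at the
  temporal pole — represented with σ = span/4 so ±2σ covers the span,
  targeting the inner third of granule dendrites and the basket cells.

The σ = extent/2 reading of the entorhinal/local extents (characteristic
reach rather than total span) is a deliberate calibration: with σ =
extent/4 the emergent granule activity clusters and their spatio-temporal
correlation extent come out ~3× smaller than the 1–2 mm structures this
system is known to produce; with σ = extent/2 the baseline STC spatial
extent reaches ≈0.6–0.9 mm (seed- and scale-dependent), approaching the
reported ~1 mm. The mossy spans are stated explicitly as spans and are
not reinterpreted.

For each postsynaptic cell a convergence count is drawn uniformly from
the pathway's anatomical range (e.g. 40–80 basket synapses per granule
cell, 750–850 mossy synapses per granule cell, 1050–1200 MEC spines +
1100–1300 LEC spines per granule cell), and that many presynaptic
partners are sampled with probability proportional to the field density at
the target's position. Multiplicity (several synapses per pair) is
allowed and logged whenever the presynaptic population is smaller than
the convergence — the expected situation at reduced scale. The
granule-to-mossy convergence is not anatomically pinned; the default is
50.

Axons are conduction delays, not compartments: delay = distance / 0.25 m/s
+ 0.8 ms fixed synaptic latency (both configurable). Removing mossy
topography (`mc_topography = "random"`) resamples each granule cell's
mossy partners uniformly over the population with in-degrees preserved.

## Stimulus

Entorhinal cells fire independent inhomogeneous Poisson trains at a 3 Hz
mean rate, ramped linearly from zero over the first 1000 ms (the ramp
prevents a large oscillatory onset transient to step input). Trains are
generated by thinning from counter-style substreams keyed by
(master seed, population, cell id), so any train can be regenerated in
isolation and results do not depend on generation order.

## Engine numerics

The integration is clock-driven at dt = 0.1 ms. Gating variables advance
analytically (`x ← x_inf + (x − x_inf)·e^(−dt/τ)`) using lookup tables on
a 0.05 mV grid built from the kinetics file. The voltage update is an
implicit backward-Euler solve with Hines elimination over each
compartment tree; channel and synaptic conductances enter evaluated at
the previous-step voltage (staggered update). Backward Euler was chosen
over exponential-Euler-with-explicit-axial-coupling after the latter
measurably distorted the multi-compartment charging curve at dt = 0.1 ms
(fitted τ_m exceeded the analytic upper bound of the compartment
ladder); the implicit solve is exact at DC and unconditionally stable,
and a half-dt check changes subthreshold 2 s voltage traces by less than
1 mV. Spikes are upward −10 mV crossings at the soma with a 1 ms refractory
period, timestamped at the step midpoint (under strong sustained
conductance drive, partially Na-inactivated cells emit reduced-amplitude
spikes that peak below 0 mV; a 0 mV criterion silences exactly the basket
cells whose output is needed to contain granule storms); each spike schedules exactly
out-degree deliveries through a ring-buffer event queue quantised at dt.

Instability (non-finite or out-of-range voltage) aborts with the
compartment and time in the error; in practice the implicit solve keeps
all acceptance scenarios inside [−120, +60] mV.

## Analytics

* **STC** — every pairwise cross-correlation of 5 ms-binned spike trains
  in a random sample of up to 10,000 active neurons, averaged within
  0.05 mm distance bins. The default normalisation is the Pearson
  correlation of binned counts (biased estimator, divisor n at all lags);
  raw covariance is available. Cells that never spike (or spike in a
  single bin) carry no correlation information and are excluded, with the
  count reported. The implementation aggregates z-scored trains per
  spatial bin and evaluates all pairs via FFT — algebraically identical
  to the literal quadratic pairwise computation (which remains available
  as `method = "direct"` and is tested against it), with distances
  measured between bin centres. Cluster extents are read off the lag-0
  and distance-0 profiles as the contiguous run staying above 1/e of the
  zero-point value (threshold configurable).
* **Spike-density spectra** — counts on a 0.05 mm × 8 ms grid; each
  spatial row is mean-subtracted, magnitude-DFT'd, and the spectra are
  averaged across rows (rows are statistically similar, so the mean is a
  variance-reduced estimate). Peak finding restricts to a 2–60 Hz band
  and requires an interior local maximum at least twice the in-band
  median magnitude — a band-edge argmax is a broadband trend, not an
  oscillation, and returns a "no peak" result rather than an error.
* **ISI histograms** — per-cell consecutive intervals pooled per
  population; total interval count equals spikes minus active cells.

## Scripted experiments

`dg_scenario()` names the standard conditions: `baseline` (no mossy
cells), `feedback`/`feedforward`/`ppdrive` (weight multipliers on the
basket-to-granule, entorhinal-to-basket and entorhinal-to-granule
pathways; sweep defaults 1–4×, 5×, 10×), `mc-rebalanced` (the tabulated
weights, which are the post-rebalancing operating point), `mc-literature`
(the pre-rebalancing condition: mossy-to-granule at 10× the rebalanced
weight — restoring a unitary EPSP comparable to a perforant-path synapse,
as literature values imply — and basket-to-granule at half strength), and
`mc-random-topo`. The exact multipliers behind the published sweep panels
are not printed; where a factor is stated (5×, 10×, 20×, halving,
doubling) the presets use it, elsewhere they use the defaults above.

The **paired-activation protocol** rebuilds the classical
commissural/perforant-path conditioning experiment inside the model: a
control run delivers a synchronous test volley from a random 15% of
entorhinal cells; conditioned runs precede it by a synchronous mossy-cell
population volley (2 ms suprathreshold somatic pulses — the model is
unilateral, so the mossy population stands in for the commissural
projection) at increasing delays, and the granule response in a 60 ms
window is expressed as percent of control. **Rebalancing** minimises the squared deviation from a target curve over
the (basket→granule, mossy→granule) multipliers with Nelder–Mead on the
log-multipliers (a multiplicative coordinate search is available but
stalls on the curved valley this objective has; on a self-consistency
fixture Nelder–Mead recovers known multipliers to ~10%). Because the
model's only inhibitory receptor is GABA_A (5.75 ms decay), the
conditioning effect lives at short (≈2–30 ms) delays — net facilitation
at the shortest delays through direct mossy excitation, inhibition around
10–30 ms — rather than the longer-lasting suppression seen in vivo.
The quantitative experimental target curve is not tabulated in the
sources; the package ships a clearly-marked synthetic stand-in
(`synthetic_rebalance_target()`: strong inhibition at short delays
recovering exponentially with a 25 ms constant) that should be replaced
with experimental values when available.

## The epileptiform absorbing state

With the associational loop wired, the desk-scale network has a sharp
stability boundary: tipping the excitation/inhibition balance toward the
mossy loop (raising mossy→granule weights, or halving basket→granule
inhibition) does not produce the graded burst-and-silence regimes seen at
the 100k–1M-cell scales, but flips the network into a sustained
epileptiform state in which granule cells fire near their refractory
limit and the conductance-clamped basket cells can no longer intervene.
This is a finite-size effect: at 1:100 scale the afferent drive is
lumpier (multiple synapses per pair under preserved convergence) and the
inhibitory population is small, so the cliff that full-scale networks
approach gradually is crossed in one step. The associated perturbation
experiments therefore reproduce the *direction* of the reported changes
but can overshoot their magnitude dramatically; the aberrant bursting
state itself is consistent with the source system's documented tendency
to enter epileptiform regimes over a wide parameter range.

## Problem sizes used by the shipped checks

The package's own test suite runs the emergent-regime checks at the 1:100
desk scale with the full 4 s horizon for the headline conditions (baseline
clusters, the feedback rhythm) and 2–2.5 s horizons for control and
storm-regime conditions whose measured quantities settle early; smaller
1:500–1:300 networks back the scripted-scenario and optimisation tests.
`scripts/acceptance.R` recomputes all reported quantities at the desk
scale with the full 4 s horizon.

## Known limitations

* No NMDA/GABA_B receptors, no short-term plasticity, no gap junctions,
  no basket–basket coupling; morphology is the reduced laminar scheme,
  not full arbors.
* Reduced-scale runs inherit multiplicity-driven drive lumpiness (above);
  absolute spike totals are scale-specific, and comparisons should be
  made within one scale with shared seeds, as the scripted experiments
  do.
* The kinetics set is a documented stand-in for unpublished gating
  parameters; single-cell acceptance rests on the passive/resting
  measurements, and network acceptance on emergent regime behaviour, not
  on spike waveforms.
* Poisson drive carries no grid-cell or theta structure; all rhythmicity
  in the model is generated by the dentate circuits themselves.
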