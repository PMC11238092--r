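---
title: "A coarse-grained model of chromatin-templated BRD4 condensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of chromatin-templated BRD4 condensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(condensim)
```

## The model

`condensim` simulates the condensation of the transcriptional activator
BRD4 on an acetylated chromatin substrate with a deliberately minimal
bead-spring representation:

* **BRD4** is two soft spheres: an N-terminal blob (the folded,
  bromodomain-containing half, WCA diameter 4.5 nm, radius of gyration
  3 nm) and a C-terminal blob (the long disordered half, 6.5 nm / 5 nm),
  joined by a FENE bond.
* **Corelets** are synthetic oligomerization platforms: one core particle
  (12 nm, the ferritin cage) with `valence` BRD4 molecules tethered to it
  by FENE bonds on their C-terminal blobs. Valence is the experimental
  control knob; phase diagrams are reported against inverse valence
  (cores per BRD4).
* **Chromatin** is a chain of nucleosome particles (10 nm) with
  sequential FENE bonds, each carrying eight 2 nm histone-tail blobs.
  Each tail is either plain (inert) or acetylated; only acetylated tails
  attract the BRD4 N-blob. The acetylation fraction is assigned as an
  exact count, `round(f * 8n)`, placed uniformly at random, so replicate
  systems have identical composition.

Three interaction classes close the model:

* **WCA** repulsion between all particle pairs (Lorentz-mixed diameters,
  `eps_rep` = 1 kT) provides sterics.
* **FENE** bonds (`K = 30 kT / sigma_b^2`, `R0 = 1.5 sigma_b`, with
  `sigma_b` the mean WCA diameter of the bonded pair; the Kremer–Grest
  convention) hold molecules together without permitting chain crossing.
* **Flory–Krigbaum** attraction between selected polymer-blob pairs,
  taken in the Gaussian-overlap form
  `U(r) = -eps * exp(-3 r^2 / (4 (Rg_i^2 + Rg_j^2)))`. Exactly two
  entries are attractive: the C-blob self-attraction (`eps_CC`, the
  stickiness of the disordered BRD4 half) and the N-blob–acetylated-tail
  attraction (`eps_NT`). Everything else is purely repulsive, in
  particular plain tails never attract anything.

Units are reduced throughout: kT = 1, lengths in nm, and time in
`tau_d`, the time a bare Corelet core needs to diffuse its own diameter.

### Interaction strengths

The two attraction strengths are the only thermodynamic knobs.

`eps_CC` is **calibrated**, not guessed: `calibrate_self_interaction()`
scans an ascending candidate list and returns the smallest value at which
chromatin-free systems condense at valence 6 but not at valence 5,
reproducing the experimentally anchored critical valence. With the
shipped desk-scale protocol the calibration selects `eps_CC = 3.5` kT
(see `scripts/calibrate.R`). Note that because the blobs sit near WCA
contact rather than fully overlapping, the pair well actually sampled is
about 0.41 of the Flory–Krigbaum prefactor (about 1.4 kT per C–C
contact at the calibrated value).

`eps_NT` has two presets: *strong* (10 kT prefactor, about a 4 kT well
at contact — a strongly bound, multivalent-capable interaction) and
*weak* (0 kT), the JQ1 mimic in which bromodomain engagement is blocked.
Switching presets changes exactly one entry of the interaction table.
The strong preset was chosen on the contact-well scale: a prefactor of
6 kT would leave only a ~2.5 kT contact well, which measurably fails to
recruit Corelets to acetylated chromatin at all (no templated pathway
would exist to study), while prefactors above ~12 kT compress dense
chromatin-bound clusters hard enough to destabilize the integrator.

### Friction and time stepping

The integrator is first-order (overdamped) Langevin dynamics:
`dx = (F / gamma) dt + sqrt(2 kT dt / gamma) xi`. Friction never enters
equilibrium averages in overdamped dynamics — it only sets relative
timescales — so it is a free transport convention. Per-particle friction
is uniform (normalized so that the bare core defines `tau_d = 1`), with
one refinement: the arm blobs of a Corelet of valence `v` carry
`1/(4v)` each, so that every Corelet totals the same whole-molecule
friction as the valence-6 reference. Two alternatives were rejected on
measurement: Stokes scaling (`gamma ~ sigma`) makes the 2 nm tail blobs
simultaneously the fastest and the stability-limiting particles,
shrinking the affordable time step ~6x with no gain in molecule
transport; and strictly uniform per-particle friction makes low-valence
Corelets (fewer beads) diffuse faster, which at desk-scale run lengths
anti-orders condensation verdicts with valence — the scans then measure
aggregation speed rather than stability. Equal molecule diffusivity
across valences removes that confound and matches the physical intuition
that a Corelet's hydrodynamic size is dominated by the assembled
platform, not its valence.

Robustness features of the stepper, all deterministic under the run
seed:

* a trial move that overstretches a FENE bond past 0.92 `R0` (a region
  whose bond energies of tens of kT are never sampled thermally) or
  moves any particle farther than the displacement cap
  (`max(0.5 nm, 6x the RMS free step)`) is rejected and retried with a
  halved time step, up to 8 halvings;
* if rejection persists — which can happen when steric compression in a
  dense cluster jams a tail against its bond limit with forces no time
  step overcomes — the smallest-dt move is applied with displacements
  clamped to the cap and any overstretched bond projected back inside
  0.95 `R0`. These emergency events are counted and reported on the
  trajectory (`n_emergency`); in production runs they are rare and
  confined to deeply compacted clusters.

Production runs use `dt = 2e-4 tau_d`; accuracy-sensitive checks (e.g.
the bonded-pair Boltzmann test) use 10x smaller steps. Two ensembles are
available: plain fixed-volume NVT, and NPxyT, in which `Lx = Ly` are
rescaled toward a target lateral pressure by a Berendsen-style coupling
(time constant `100 dt`) while `Lz` stays fixed so the chromatin tension
does not couple to box fluctuations. The shipped nucleation protocols
use NVT: over the short transition paths measured here the
supersaturation drift from monomer depletion is modest, and a barostat
on a desk-sized box adds fluctuation artifacts larger than the drift it
removes.

### Chromatin slack

A periodic chain whose contour just spans the box is taut and **cannot
compact**, no matter how strongly it is bridged; more generally the
compaction a chain can express is capped by its slack. The reference
experimental systems thread several-fold more contour than box length
through their simulation volumes. Desk-scale systems here use a
contour-to-span ratio of 2 (`CHAIN_SLACK`), laid out as a helix with an
integer number of turns (so the periodic closure matches) whose radius
stays within a quarter of the lateral box. This is enough slack for
bridging-induced compaction to express itself, while keeping the
nucleosome count — and hence the particle budget — affordable.

## Desk-scale study conditions

The reference experiments run hundreds of Corelets and 400 nucleosomes
for very long equilibrations on cluster hardware. All protocols shipped
with this package are desk-scale: they preserve the composition ratios
(valence, acetylation fraction, stable-nucleus proportion) at reduced
particle counts, sized so a full analysis runs on one CPU in minutes.
The concrete sizes used are:

* **Critical-valence scans (chromatin-free):** 48 Corelets in a
  58 x 58 x 476 nm box (reference concentration 3e-5 molecules/nm^3),
  40-50 tau_d per run, 2-3 replicas per valence.
* **Chromatin scans:** 12 Corelets around a 24-nucleosome chain
  (58 x 58 x 118 nm, same concentration), 500k steps, 3 replicas.
* **Nucleation ensembles:** 32 valence-6 Corelets around a
  32-nucleosome chain at supersaturation S = 1.75 (initial gas
  ~3e-5 /nm^3, just below the `R_clust` percolation density), 140k
  steps per replica, 10 replicas per condition.

Two methodological consequences of the scale reduction deserve emphasis.

**Condensation scans start dispersed.** The classic direct-coexistence
protocol scores whether a pre-built slab persists. At desk scale a
pre-built slab is kinetically frozen over any affordable run length
(evaporation of a condensed phase is activated and slow), so slab
persistence cannot discriminate valences: measured at 48 Corelets over
48 tau_d, every `eps_CC` from 0.1 to 3 kT and every valence reads
"persistent". The shipped scans therefore start from a dispersed gas at
a fixed reference concentration and ask whether a condensate *forms* —
the kinetically accessible, downhill direction — scored by the 3-fold
density criterion along z (either the Corelet or the nucleosome profile)
sustained over the final third of the run. For scan verdicts the 3-fold
threshold is applied to the dense/dilute plateau means rather than the
single densest and dilutest bins: with a few dozen molecules, a
non-condensing gas keeps persistent single-bin voids over the averaging
window, which would trip a literal max/min rule spuriously.
`detect_condensate()` itself implements the literal, inclusive max/min
rule for use on well-averaged profiles. `build_slab_system()` still constructs the slab
geometry, which is used to read coexistence densities once a dense phase
exists.

**Pathway classification uses coverage in excess of chance.** A
transition path is on-chromatin if the largest cluster's mean nucleosome
coverage (nucleosomes within `R_cut` = `R_clust` of a member reference
point) over `[t_start, tau_nucl]` exceeds the threshold (default 1
nucleosome). In a desk-sized box *any* stable cluster grazes the chain:
the incidental coverage of a randomly placed cluster is 3–9 nucleosomes,
so raw coverage classifies even zero-attraction controls as
on-chromatin. `largest_cluster_trace()` therefore also records the mean
coverage of the same cluster rigidly translated to random lateral
positions (`coverage_null`), and classification applies the threshold to
the observed coverage *minus* this null. Two further desk-scale
adjustments: the averaging window extends over the whole recorded
nucleation-and-growth segment (the transition path alone spans a handful
of frames, whose noisy average misclassifies ~20% of zero-attraction
controls), and an on-chromatin call additionally requires at least one
mean acetylated-tail contact (tails within 5 nm of a member N-blob) —
clusters are nearly immobile on the run timescale, so one born next to
the chain by chance stays there, and only molecular contact separates
chance proximity from chromatin-bound assembly. In a full-scale box the
null is essentially zero, genuinely templated clusters are contact-bound
by construction, and the rule reduces to the plain coverage threshold.

## Nucleation analysis

Clustering is single linkage over one reference point per molecule (the
core particle of a Corelet; the C-blob of a free BRD4), with cutoffs of
25 nm (Corelets) and 12.5 nm (free BRD4) — the distances at which
nonbonded intermolecular interactions are negligible in any orientation.
The stable-nucleus size scales with system size from the full-scale
proportions (200 of 512 Corelets; 600 of 5832 BRD4) with a floor of 10
molecules. The transition path starts at the last departure of `N_CS`
from the metastable band (mean ± 3 SD over the first 5% of frames)
before it first reaches the stable size; `tau_nucl` is that first
crossing, and `J = 1/mean(tau_nucl)` over nucleating replicas with a
jackknife standard error. Censored (non-nucleating) replicas are counted
and reported, never imputed — under the weak preset a majority of
replicas typically fail to nucleate within the run, which is itself a
faithful qualitative feature of the JQ1 condition.

The delay time extrapolates the post-nucleation growth segment under
diffusion-limited growth (radius ~ t^(1/2), so `N ~ t^(3/2)`):
`N_CS^(2/3)` is fitted linearly in time, anchored at
`(tau_nucl, stable_size^(2/3))`, and `tau_delay` is the extrapolated
crossing of `observable_multiplier x stable_size` (default 15x, the
ratio of the smallest microscopically registerable droplet to the stable
nucleus). Anchoring makes the multiplier-1 case collapse exactly onto
`tau_nucl` and reproduces constructed power-law traces exactly.

## Quantification module

The experiment-side statistics are implemented against synthetic images
(`synthesize_nucleus_image()`: Gaussian puncta on constant background
with additive noise, ground truth returned) or projections of simulation
states (`project_simulation()`): Gaussian smoothing, morphological
rolling-ball background subtraction (disc radius 4 px), IsoData or Otsu
thresholds, 8-connected labelling; puncta count, mean area, and the
condensate volume estimate `count x mean_area^(3/2)`; Pearson
correlation between image regions; nucleation-kinetics fits (delay =
first frame starting two consecutive strict increases; slope over the
maximal-R^2 window from the delay frame, which removes the manual choice
of the "linear portion"; number density = final-frame count); and a
logistic regression of the phase flag on log concentration and inverse
valence, reporting the 50% contour, with perfectly separable inputs
returned as a separating threshold plus flag instead of divergent
coefficients.

The synthetic generator emulates well-separated diffraction-limited
puncta with stationary background and Gaussian noise. It does not
emulate nuclear heterogeneity, photobleaching, expression-level
confounds, or overlapping puncta — so passing segmentation tests
demonstrate correctness of the pipeline, not robustness to real
micrograph pathology, which is out of scope.

## Numerical choices

* Flory–Krigbaum terms are truncated where `|U| < 1e-4` kT and shifted
  to zero; forces are exact gradients of the truncated-shifted energy.
* Pair evaluation uses Verlet lists (4 nm skin, half-skin displacement
  rebuild) with a separate long-cutoff list for the C-blob
  self-attraction, whose range (~25 nm at the calibrated strength) far
  exceeds the steric range.
* Density profiles re-centre each frame on the circular centre of mass
  along z before averaging, so slab or condensate drift does not smear
  the profile. Plateau estimates use the 70%/30% thresholds with
  interfacial-bin exclusion.
* Coexistence-density plateaus: dense = bins above 70% of max, dilute =
  bins below 30% excluding interface-adjacent bins.
* The acetylation pattern, initial placement, thermal noise and replica
  seeds all derive deterministically from user seeds via a
  counter-based (splitmix64) splitter; equal seeds give bit-identical
  trajectories.

## Known limitations

* Valence is monodisperse; polydispersity (which broadens the apparent
  phase boundary) is not modelled.
* Chain dynamics are Rouse-slow: full coil equilibration times scale as
  the squared nucleosome count and exceed any desk-scale run. Chromatin
  compaction observables therefore reflect partial, kinetically limited
  compaction. Together with the small-number counting statistics of
  desk-scale density profiles (tens of molecules over ~10 bins), this
  makes the with-chromatin critical-valence scan the least robust
  analysis in the package: decoration of the chain by low-valence
  Corelets can transiently trip the 3-fold criterion, and
  bridging-induced condensates at valence 2 are themselves transient at
  this scale. The chromatin-free critical valence and the
  nucleation-pathway switch are substantially more reproducible.
* No electrostatics, hydrodynamics, angular potentials, nucleosome
  unwrapping, or sequence detail; the mapping from simulated number
  densities to micromolar concentrations is left as a documented
  conversion rather than a fitted quantity.
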