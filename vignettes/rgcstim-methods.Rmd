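---
title: "Modeling extracellular stimulation of retinal ganglion cells with rgcstim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling extracellular stimulation of retinal ganglion cells with rgcstim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcstim)
```

## The scientific problem

Epiretinal prostheses stimulate surviving retinal ganglion cells (RGCs)
with brief current pulses from disk electrodes placed on the vitreal
surface.  Which part of a cell the stimulus actually excites — the axon
initial segment (AIS), the axon proper, the soma, or the dendrites —
determines the threshold current, the response latency, and ultimately
whether a stimulus activates one cell or recruits many cells through
their passing axons.  `rgcstim` implements the full simulation chain
needed to study these questions: morphologically detailed
conductance-based RGC models, the analytic extracellular field of a disk
electrode, binary-search threshold mapping over 2-D electrode scans, and
population analyses over jittered mosaics of identical cells.

Because no traced morphologies are distributed with the package, a
parametric generator (`generate_rgc()`) produces synthetic cells with the
structural features that matter for extracellular stimulation: a
cylindrical soma, an axon running in the retinal plane with a hillock and
a high-sodium AIS at a fixed path distance, a planar stratified dendritic
tree of controllable field diameter, and a long (900 um) axon
continuation.

## Model components

### Morphology and discretization

A morphology is an SWC-style tree of tapered cylinders (micrometre
units).  The retina lies in the x–y plane with +z pointing toward the
vitreous, so the stimulating electrode sits at positive z (40 um above
the somatic center by default) and dendrites stratify at negative z.
The soma is a cylinder whose length equals its diameter, which makes its
lateral area equal to the surface of the equivalent sphere.  SWC type
codes carry soma/axon/dendrite identity; hillock and AIS labels are
derived from path distance because SWC has no AIS code — the AIS spans
25–75 um of path from the somatic center and takes precedence over the
hillock label where the nominal spans overlap.

`segmentize()` splits every section into compartments shorter than 12 um
(the default granularity at which the cell samples the extracellular
potential).  Axonal sections are cut exactly at the 25/75 um region
boundaries, so the AIS extent does not depend on the segmentation
granularity; per-section membrane area is conserved exactly.  Neurites
attach to the soma compartment containing the somatic center so the
attachment point is stable under re-segmentation.

### Membrane biophysics

Each compartment carries five voltage-gated currents plus an ohmic leak:
transient Na, delayed-rectifier K, A-type K, L-type Ca, and
Ca-gated K.  Conductance densities (mS/cm²) are region-specific:

| region   | gNa | gK | gA | gCa | gKCa |
|----------|----:|---:|---:|----:|-----:|
| dendrite | 40 (40–80) | 12 | 36 | 2 | 0.05 |
| soma, hillock | 70 | 18 | 54 | 1.5 | 0.065 |
| AIS      | 700 | 18 | 54 | 1.5 | 0.065 |
| axon     | 70 | 18 | 0  | 0   | 0.065 |

with gL = 0.005 everywhere, ENa = 35, EK = −75, EL = −62.5 mV,
Cm = 1 µF/cm² and Ra = 110 Ω·cm.  Gating kinetics follow the
Fohlmeister–Miller five-channel RGC formalism; the rate functions are
evaluated through their finite limits at removable singularities, and a
uniform rate-scaling factor is exposed in place of an explicit Q10 (the
nominal temperature, 35 °C, enters the Nernst relation for ECa).

The Ca-gated K current activates with a saturating Hill function of the
submembrane calcium pool, `(Ca/Kd)² / (1 + (Ca/Kd)²)` with Kd = 1 µM.
The pool loads from inward Ca current through a 0.1 um shell and relaxes
toward a residual concentration with a 1.5 ms time constant.  The
residual concentration is a deliberate design choice: at the textbook
0.1 µM the model is a slow (~5 Hz) pacemaker, which is incompatible with
a stimulation protocol that defines threshold as "any somatic spike in a
40 ms window".  With the residual at 0.5 µM the resting K(Ca)
conductance holds the cell quiescent (rest near −71 mV, slightly below
EL) while leaving repetitive firing under 20–60 pA somatic injection and
µA-scale extracellular thresholds intact.  This is the package's
operating point; it can be changed through the `membrane_spec()` kinetics
table.

### Cable solver

`assemble()` turns a segmented cell into axial conductances
(half-cylinder resistances in series), per-compartment capacitances and
region-resolved channel tables, with sealed-end boundaries.  `cable_run()`
advances the voltage with a Crank–Nicolson update solved in O(N) per step
by Hines elimination on the tree; gates and the calcium pool advance by
their exact exponential relaxations (staggered update).  The default
time step is 0.025 ms.

The extracellular potential couples through the axial terms: currents
flow down gradients of (Vm + Ve), so a spatially uniform Ve produces *no*
response — this null property is exact in the discretization and is
verified to below 1e-9 mV.  Because the 0.1 ms pulse drives a stiff
membrane transient, steps in which the pulse is active (and the first
step after it) are integrated with four fixed micro-steps; this is a
fixed refinement of the scheme, not adaptive stepping, and it brings the
dt-sensitivity of threshold estimates at the default step below 0.5%.

Every protocol starts from a rest state obtained by a 200 ms
stimulus-free settling run (cached per system); the settled rest drifts
by less than 1 mV over a 40 ms window.

### Extracellular field

The disk electrode is an equipotential disk on a semi-infinite ohmic
half-space (the Newman/Wiley–Webster solution),

$$V(r, z) = \frac{2}{\pi}\, I R_s \arcsin
  \frac{2a}{\sqrt{(r-a)^2+z^2} + \sqrt{(r+a)^2+z^2}},$$

normalized so V = I·Rs on the disk surface.  The calibrated transfer
resistance is 0.725 MΩ for a 10 um radius disk (so I in µA times Rs
gives volts; `disk_potential()` returns mV) and scales with electrode
surface area, Rs(a) = Rs₀ (a₀/a)².  The MΩ scale is the dimensionally
consistent reading of the calibration: µA-scale thresholds require tens
of millivolts of extracellular drive at the cell, and MΩ-scale transfer
resistances are typical of small disks in high-resistivity retinal
tissue.

Depth-dependent tissue inhomogeneity multiplies Rs by a coefficient
C(z) = 1/ratio + (1 − 1/ratio)·exp(−(z/width)²): resistivity peaks at
the somatic layer (C(0) = 1, so the calibrated Rs is the peak value) and
falls to the distant-layer value with a 20 um width.  The stimulus is a
charge-balanced cathodic-first biphasic pulse, 0.1 ms per phase, no
inter-phase gap, delivered at t = 1 ms of each run.

### Thresholds and spike criteria

A spike is an upward 0 mV crossing of the somatic membrane potential.
During the pulse itself the imposed field drives a large *passive*
somatic deflection that can cross 0 mV and revert immediately; such
crossings are not action potentials, so the threshold machinery only
counts crossings after the pulse offset.  Reported latencies (stimulus
onset to spike peak) are therefore always at least the pulse duration,
matching how response latencies are quoted for biphasic stimulation.

`find_threshold()` brackets the threshold by doubling from 1 µA (capped
at 200 µA; a position that cannot evoke a spike at the cap is reported
not-excitable, not an error) and then bisects to the requested
resolution — 0.1 µA for the 10 um electrode, 0.5 µA for larger ones.
The returned threshold is the spiking upper bracket, so "threshold
spikes, threshold − tol does not" holds by construction; agreement with
an exhaustive linear scan at tol/4 steps is part of the test suite.
Binary search assumes spiking is monotone in amplitude; the final
bracket is validated by construction and the assumption can be probed
with a fine linear scan where needed.

### Mosaics and population analysis

`build_mosaic()` tiles copies of a template cell on a lattice and jitters
each position with Gaussian noise (5 um SD for large-field cells, 1 um
for midget mosaics).  Spatial coverage is summarized by the dimensionless
coverage factor, density × mean dendritic-field area (field area taken
as the circle of the mean field diameter); `spacing_for_coverage()`
inverts this to target a coverage factor — the study mosaics use 1.28
(a realistic value for large-field RGC types), giving ~150 um spacing
for a 191 um field.  The lattice spacing itself is exposed as a
parameter and chosen through the coverage factor.

Cells are electrically independent: each cell is simulated separately in
the shared imposed field with its own planar offset.  The population
threshold at a position is the minimum current activating at least one
cell (binary search on the "any cell spikes" predicate), and the
activated set "at threshold" is evaluated at the spiking upper bracket,
which guarantees at least one active cell.  Cells whose peak field
magnitude at a probe amplitude stays below 2 mV are skipped — a spike
from rest needs tens of millivolts of local drive, so the bound is
conservative, amplitude-dependent and deterministic.  Identity maps are
keyed by the sorted tuple of activated cell ids; distance-to-axon uses
in-plane point-to-segment distance over all axon polylines.

Threshold maps and population maps evaluate positions independently
(`workers` forks a process pool with a fixed task order), so results are
identical for any worker count.

## What the synthetic cells do and do not show

The generator reproduces the structural determinants of extracellular
excitability — soma size, AIS position and span, axon trajectory and
length, dendritic field diameter and stratification — with lightly
jittered recursive bifurcation standing in for real dendritic branching
statistics.  The qualitative phenomena (AIS as the global threshold
minimum, the axonal low-threshold corridor, migration of the minimum
away from the AIS for large electrodes, robustness to tissue
inhomogeneity and dendritic excitability, predominantly single-cell
activation at threshold, nested supra-threshold recruitment through
passing axons) all emerge on these cells.

Quantities tied to specific traced cells are *not* reproduced.  The
clearest case is dendrite removal: on synthetic cells the dendritic tree
contributes a distributed axial current source during the brief cathodic
phase, and removing it raises the mean AIS threshold by roughly 20%
(strongly dependent on soma diameter — over 200% with a 15 um soma,
~15% at 25 um).  Experimentally traced large-field cells show a much
weaker dependence of AIS threshold on the dendritic tree; that reflects
morphological detail a parametric generator does not capture, and the
corresponding acceptance test is left failing rather than weakened.

## Numerical and design choices, in brief

- Soma diameter defaults: 20 um (large-field, alpha-like) and 10 um
  (midget); stratification depth defaults to 15 um below the somatic
  plane and is a free parameter.
- Axon-depth edits (`edit_shift_proximal_axon()`) taper the displacement
  linearly over 20 um beyond the shifted span so the axon stays
  continuous rather than jumping discontinuously.
- Rest state: 200 ms stimulus-free settling before every protocol
  defines the initial condition.
- Electrode z-offsets are positive (vitreous side); cathodic currents
  are negative, so the first pulse phase makes Ve negative near the
  electrode.
- Problem sizes in the tests and the acceptance script are desk-scale:
  ~185-compartment cells, coarse 20 um grids of some tens of positions,
  9-cell mosaics with ~30 interior test positions.  The phenomena of
  interest are position-level properties and are insensitive to grid
  density beyond this scale.
- Traces, maps and mosaics export to CSV/SWC (plain text throughout).

## A minimal session

```{r example, eval = FALSE}
cell <- standard_rgc()                  # 191 um field, 900 um axon
sys <- assemble(segmentize(cell))

# threshold with a 10 um electrode over the AIS midpoint
find_threshold(sys, c(50, 0), radius = 10, tol = 0.1)

# mean AIS threshold (proximal / mid / distal sites)
ais_threshold(sys, radius = 10)

# a tiling mosaic and its population threshold at one position
mos <- build_mosaic(cell, 3, 3,
                    spacing = spacing_for_coverage(cell, 1.28),
                    jitter_sd = 5, seed = 7)
population_threshold(mos, c(20, 30))
```

The numbered scripts under `analysis/` run the full study: cell
construction (`01`), single-cell threshold maps and manipulations
(`02`), response propagation and latencies (`03`), and the population
analyses (`04`), writing their tables under `results/`.
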