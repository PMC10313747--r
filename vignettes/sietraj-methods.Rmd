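---
title: "Methods: trajectory analysis, SIE scoring, and gate landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis, SIE scoring, and gate landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sietraj)
```

## Scope and model

`sietraj` analyses molecular-dynamics trajectories of a receptor–ligand
complex with the aim of ranking ligand candidates and characterising a
two-state "gate" in the receptor. The motivating system is the wasp-venom
phospholipase A~1~ (Ves a 1, from *Vespa affinis*), whose T83–E93 and
G251–C261 loops act as a gate over the catalytic pocket: their centroid
separation populates a closed basin near 19 Å and an open basin near 22 Å.
All machinery is, however, generic: any receptor with two designated loop
selections and a ligand group fits the same pipeline.

The package deliberately does **not** simulate dynamics. It consumes
trajectories (multi-model PDB or multi-frame XYZ) produced elsewhere,
together with a per-atom parameter table (partial charges, Lennard-Jones
parameters, van der Waals and Born radii) supplied as a sidecar TSV. This
keeps the analysis engine-agnostic: any force field whose assignments can
be exported to a table is usable.

## Stability and fluctuation metrics

Superposition uses the Kabsch algorithm (SVD of the weighted cross
covariance with a sign correction, so reflections are never returned).
Defaults follow common practice:

* **RMSD series** – each frame is fitted on the receptor CA atoms; the
  deviation is measured over a separately configurable selection.
* **RMSF** – computed per residue (CA atoms) about the *time-average*
  structure after per-frame superposition, not about the initial frame;
  the initial frame only anchors the fit.
* **Loop distance** – the Euclidean distance between the CA centroids of
  the two gate-loop selections.

A frame at or above the open/close boundary (default 20.5 Å, the midpoint
of the two basin positions) is labelled *open*; ties go to open. Only the
two basin positions are physically motivated; the midpoint boundary and
the tie rule are package conventions.

## Solvent-accessible surface area

SASA uses the Shrake–Rupley method: each atom's van der Waals sphere is
inflated by the probe radius (1.4 Å) and covered with a deterministic
Fibonacci lattice (960 points by default; the isolated-sphere error is
well under 1%). The binding-site series reports, per frame, the summed
SASA (computed in the full complex) of the receptor residues having any
atom within 5.0 Å of any ligand atom — whole-residue granularity,
membership recomputed every frame. Shrake–Rupley was chosen for its
transparency and testability against closed forms; other SASA definitions
(e.g. the LCPO approximation common in MD packages) give systematically
similar but not identical numbers, so absolute SASA values should only be
compared within one method.

## Interaction criteria

* **Atom contacts**: a receptor atom is in contact when its minimum
  distance to any ligand atom is ≤ 3.50 Å. Heavy atoms only by default;
  typical reported contact counts (≈17–19 for a well-seated ligand)
  correspond to heavy-atom counting.
* **Hydrogen bonds**: donor–acceptor distance ≤ 3.50 Å *and*
  donor–H⋯acceptor angle (measured at the hydrogen) ≥ 150.00°, both
  boundaries inclusive. Donors are N/O with a covalently bonded hydrogen
  (a bond list is required); acceptors are N/O. Sulfur is excluded.
* **Occupancy**: the percentage of window frames in which a pair
  satisfies both criteria. The analysis window defaults to the final 10%
  of the trajectory (the equilibrated tail, e.g. the last 10 ns of a
  100 ns segment).
* **Interaction map**: per receptor residue ever within the contact
  cutoff, the H-bond occupancy (either donor direction) and the
  percentage of frames with at least one carbon–carbon contact
  ("hydrophobic" occurrence).

## Solvated interaction energy

The binding free energy estimate is

$$\Delta G_\mathrm{bind} = \alpha\,(E_\mathrm{vdW} + \gamma\,\Delta SA
  + E_\mathrm{ele} + G_\mathrm{RF}) + C$$

with the standard SIE calibration $\alpha = 0.105$,
$\gamma = 0.013\ \mathrm{kcal\,mol^{-1}\,Å^{-2}}$,
$C = -2.89\ \mathrm{kcal\,mol^{-1}}$ as package defaults.
$E_\mathrm{vdW}$ and $E_\mathrm{ele}$ are the intermolecular
Lennard-Jones and Coulomb sums over all receptor–ligand pairs, with no
cutoff and an interior dielectric of 1 (nonbonded cutoffs belong to the
MD engine, not to end-point analysis energies). $\Delta SA$ is the
surface area buried on binding. The combiner `sie_combine()` accepts
externally computed components, so published component tables can be
rescored independently of any solvation model choice;
`sie_reference_components()` ships such a table for the Ves a 1 study
system (DMPC control plus five drug candidates, three replicates each;
one replicate is internally inconsistent at the printed precision and is
flagged).

The reaction-field term is a Still-type generalized-Born surrogate with
fixed per-atom Born radii, $\varepsilon_\mathrm{in} = 2.25$ (the interior
dielectric the SIE coefficients were calibrated with) and
$\varepsilon_\mathrm{out} = 78.5$. With rigid groups and fixed radii the
binding delta reduces exactly to the receptor–ligand cross terms, which
makes the per-residue split well defined. A boundary-element
Poisson–Boltzmann solver would be the reference implementation for this
term; the GB surrogate keeps the package dependency-free and is exact in
the single-ion (Born) limit, but absolute $G_\mathrm{RF}$ values on real
systems will differ from PB numbers.

Trajectory scoring draws 100 evenly spaced snapshots (first and last
window frame included) from the analysis window and reports the mean and
standard deviation of the per-snapshot estimate.

**Per-residue decomposition** assigns to each receptor residue its
ligand-pair Lennard-Jones plus surface-burial share (`vdw_term`) and its
ligand-pair Coulomb plus GB-polar share (`ele_term`); the pairwise parts
sum exactly to the intermolecular totals (a conservation property tested
to 10⁻⁶). Residues with total contributions strictly below
−1.00 kcal/mol are flagged as *key residues* (a residue at exactly the
threshold is excluded).

## Free-energy landscape

With $g(x, y)$ the normalised joint histogram of loop distance vs loop
RMSD (0.10 Å bins on zero-anchored edges, so grids align across runs),
the landscape is

$$\Delta G(x, y) = -k_B T \ln \frac{g(x, y)}{g_\mathrm{max}}$$

at $T = 310$ K: the most populated bin sits at zero and every occupied
bin is non-negative, which is the only self-consistent reading of a
"minimum set to zero" convention. Empty bins are masked (NA), never
infinite, so exports stay finite. The landscape RMSD coordinate is
computed over both loops' CA atoms jointly against the first frame, after
fitting on the receptor CA set.

**Basin detection** takes occupied bins that are 8-neighbourhood minima,
collapses connected equal-depth plateaus to their lowest-index bin, and
merges representatives within 10 bins (1 Å), keeping the deeper one. Two
numerical guards matter in finite samples: (i) a bin with only empty
neighbours is vacuously a minimum, so candidates holding less than 5% of
the modal bin's probability (depth > $k_BT\ln 20 \approx 1.85$ kcal/mol)
are discarded — isolated tail bins otherwise masquerade as basins;
(ii) the 1 Å merge radius is small against the 3 Å separation of the
gate basins but large enough to absorb histogram roughness inside one
basin.

## Synthetic data: what it emulates, and what it does not

The generators produce a fully parameterised toy complex and trajectories
with *known* ground truth, which is what makes the whole pipeline
testable without external data:

* a pocket of residues whose CB atoms rest at 3.05 Å from the ligand
  ring — just inside the 3.50 Å contact cutoff with enough margin that
  frame jitter cannot flip resting contacts, so the contact count stays
  at its target (±2, one unit per scripted H-bond engaged);
* two gate loops whose CA centroids follow a two-state Markov chain
  (means 19.0/22.0 Å, within-basin σ = 0.4 Å). Markov switching was
  chosen over Langevin dynamics deliberately: the analysis consumes only
  the stationary distribution and the switching structure, not kinetics.
  The default switching scale (0.2) keeps state dwell times around 5–17
  frames, so a 30,000-frame run carries an effective sample size of
  thousands and occupancy estimates concentrate tightly around the
  stationary target;
* scripted hydrogen bonds: per frame, each donor/hydrogen/acceptor
  triple is engaged by an independent Bernoulli draw at its target
  occupancy; engagement places the mobile partner exactly on the
  donor–hydrogen axis at 2.80 Å (angle 180°), disengagement at 4.30 Å.
  The receptor-side anchor atoms are exempt from jitter, so the
  geometric truth label of every frame is exact by construction;
* isotropic per-atom Gaussian jitter; for iid jitter of per-coordinate
  σ the expected RMSF is $\sqrt{3}\sigma$, giving an analytic target
  (σ ≈ 0.52 Å reproduces the ≈0.9 Å loop fluctuations typical of a
  mobile gate loop).

What the toys do *not* emulate: realistic force-field energetics (the toy
SIE values are internally consistent but arbitrary in magnitude),
correlated backbone motion, solvent structure, or conformational
selection coupling between gate state and ligand pose. Passing tests
therefore validate the *estimators* — that each module recovers known
statistical structure at stated tolerances — not any claim about real
proteins.

## Numerical choices and degenerate inputs

* Coulomb constant 332.0636 kcal Å mol⁻¹ e⁻²; $k_B$ =
  0.0019872041 kcal mol⁻¹ K⁻¹.
* Superposition requires ≥3 non-collinear positions; collinear input is
  an error, planar input is fine.
* Coincident receptor/ligand atoms (r = 0) are hard errors in every
  energy term.
* Snapshot selection is deterministic (evenly spaced, endpoints
  included); generators save and restore the caller's RNG state, and all
  outputs are byte-reproducible for a fixed seed.
* Problem sizes used by the shipped checks: 30,000-frame gate runs for
  landscape structure (matching a 300 ns trajectory at 10 ps spacing),
  2,000-frame windows for occupancy recovery, 5,000 frames for the RMSF
  law, 100 SIE snapshots; unit tests use smaller replicas of the same
  constructions.

## Known limitations

* The GB reaction field is a surrogate, not a PB solver; use externally
  computed components with `sie_combine()` when PB-grade numbers exist.
* SASA is Shrake–Rupley; values are not interchangeable with LCPO or
  power-diagram areas.
* Binary trajectory formats (DCD/NetCDF) are out of scope; convert to
  multi-model PDB or XYZ first.
* The FEL is a direct Boltzmann inversion of sampled histograms — it
  assumes equilibrium sampling and offers no reweighting for biased
  simulations.
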