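---
title: "Models and methods: coarse-grained dendrimer micelles and siRNA binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrimicelle)
```

## The system and the model

Amphiphilic dendrimers (ADs) are lipid/dendrimer hybrids: a hydrophilic
PAMAM dendron head of generation g — carrying 2^(g+1) terminal amines, all
protonated at physiological pH — bonded through an aromatic ring to a single
alkyl tail of 13, 15 or 18 carbons. At the 4-to-1 coarse-grained (CG)
mapping used here, each bead replaces roughly four heavy atoms:

* the alkyl tail becomes 3, 4 or 5 apolar C1 beads (13C, 15C, 18C),
* the ring becomes one hydrophobic bead,
* the dendron becomes a binary tree of neutral amide (Nda) node beads, one
  per branch point, terminated by one charged Qd bead (+1 e) per amine.

The head-tree mapping deserves a note: published CG parameter sets for PAMAM
dendrons define the branch connectivity but the bead-per-group reduction at
each generation is a modelling choice. We adopt the simplest tree that
preserves the two quantities every downstream analysis relies on — the
number and charge of terminal amines (2^(g+1), all +1) and the
hydrophilic/hydrophobic partition of the molecule. Bond equilibria use
standard CG values (0.35 nm within the dendron, 0.47 nm along the tail,
k = 1250 kJ mol⁻¹ nm⁻²), with gentle 180° angles keeping the tail extended.

The siRNA duplex (20 base pairs plus dTdT overhangs) maps each nucleotide to
one Qa phosphate (−1 e), one P1 ribose bead and a base-dependent complement:
purines three beads (A: Na–Na–Nda, G: Nda–Nda–Na), pyrimidines two (C:
Na–Nd, U: Na–Na). dT overhangs take the uridine complement; every residue,
including the 5′-terminal one, carries a phosphate bead so the 20-bp core
holds exactly 40 phosphates — the denominator of all N/P arithmetic.
Overhang phosphates exist in the topology but are excluded from that
denominator. Duplex shape is maintained by an elastic network: every bead
pair within 0.7 nm of its reference conformation is restrained with a
harmonic term of 1500 kJ mol⁻¹ nm⁻², the equilibrium set to the observed
distance; more distant pairs interact only non-bondedly.

When no structure is supplied, the reference conformation is an idealized
A-form helix (rise 0.28 nm/bp, twist 32.7°/bp, phosphate backbone at
0.92 nm, base beads stepping toward the axis). Any helical geometry with
realistic intra- and inter-residue spacings serves the purpose — fixing the
elastic-network connectivity — and the generated one keeps neighbouring
beads at 0.2–0.35 nm. Atomistic coordinates, when available, are reduced by
mass-weighted centre-of-mass mapping of fixed heavy-atom groups
(`map_atomistic_duplex()`), the standard CG reduction.

## Micelle descriptors

All radii derive from mass-weighted radii of gyration under the uniform
solid-sphere convention R = √(5/3)·Rg — applied to all beads of an
aggregate for the micelle radius R_m, and to the hydrophobic (tail + ring)
beads for the core radius R. The proportionality constant is configurable;
√(5/3) is the standard estimator for a filled sphere and reproduces the
magnitudes of the reference tables. The ring bead counts as core material
throughout.

From the core radius follow the spherical-core relations V = (4/3)πR³ and
A = 4πR² (exactly consistent with R = 3V/A), the per-molecule quantities
v₀ = V/N and a = A/N, and the packing parameter

P = v₀ / (a·l₀),

which for a spherical core reduces to R/(3·l₀). The critical tail length l₀
is measured as the mean ring-to-terminal-tail-bead distance over member
molecules. Shape classes follow the packing rules exactly as stated:
P ≤ 0.33 sphere, 0.33 < P ≤ 0.50 cylinder, beyond that bilayer — the
boundaries are closed on the sphere and cylinder sides, so P = 0.33
classifies as a sphere and P = 0.34 as a cylinder.

Aggregates with relative shape anisotropy κ² > 0.2 (from the gyration
tensor) are additionally flagged as rods and report min/max cylinder radii,
estimated per axial third of the core with the uniform-disc relation
R_cyl = √(2·⟨r_⊥²⟩). The packing parameter is still computed from the core
V/A so that rod rows remain comparable.

Derived indices: interdigitation I_d = l₀/R (I_d = 1 means tails just reach
the core centre-line; larger values mean interpenetration), surface charge
density σ_m = e·N/S_m with e = 2^(g+1) and S_m = 4πR_m², area per amine
S_m/(N·e), and the N/P ratio computed — following the published convention —
as the total number of ADs in siRNA-bound micelles divided by the 40 core
phosphates. Note two arithmetic caveats inherited from the reference data
and recorded in the curated tables' `consistent` flag: a few printed rows do
not reproduce their own printed packing parameter or area-per-amine from
their printed inputs (one-decimal rounding cannot explain deviations above
0.015), and the published σ_m worked values do not follow from e·N/S_m with
the printed areas; the formula is implemented as stated and those specific
numbers are not used as checks.

## Interaction measures

* **SASA** is Shrake–Rupley: each bead contributes a sphere of radius
  (bead radius + probe) sampled at 480 quasi-uniform Fibonacci points;
  points inside any other context bead's probe-inflated sphere are buried.
  Bead radii default to 0.26 nm (half the standard CG Lennard-Jones σ,
  rounded up) and the probe to 0.26 nm (half a water-bead diameter); both
  are configurable. Coincident beads are resolved deterministically (the
  lower-indexed bead keeps the shared surface), so two fully overlapping
  beads report the area of one. At the default sampling density the measure
  is translation/rotation-stable to ~0.5 % and agrees with high-density
  Monte-Carlo integration to well under 2 %.
* **Contacts** are minimum-image pair counts at 0.75 nm (inclusive). Two
  semantics are exposed because published contact figures can mean either:
  `count_contacts()` counts pairs; `amine_binding_stats()` counts unique
  amine beads per micelle, the semantics of per-micelle binding tables
  (bounded by 2^(g+1)·N per micelle). A micelle counts as siRNA-bound when
  its COM distance to the duplex is ≤ 5 nm, the upper edge of the observed
  bound range; standard errors are taken over decorrelated (strided)
  frames.
* **Solvation shells** use 0.65 nm, the first CG solvation shell, one
  consistent value everywhere it appears (shared-ion counts in fusion
  profiles, water/ion shells around siRNA).
* **RDF maps** normalize shell counts by shell volume and the species' bulk
  density in the box, per base pair, around the mass-weighted COM of the
  two paired nucleotides. A spatially uniform species converges to
  g(r) = 1; the acceptance suite checks the outer-bin mean to ±0.05.
* **COM distances** are taken between mass-weighted centroids of groups
  made whole across the periodic boundary, then reduced to the minimum
  image; the series is invariant to lattice translations of the whole
  system. Plateaus are found by a sliding-window slope test (|slope| <
  0.01 nm/ns over ≥ 10 frames) — an operational definition chosen because
  "plateau" is otherwise a narrative term.

## Aggregate detection and tracking

The clustering criterion is single linkage on hydrophobic beads: two ADs
are linked when any tail/ring bead pair sits within 0.6 nm (the first CG
neighbour shell) under minimum image; aggregates are connected components,
singletons allowed. The criterion and cutoff are configuration knobs — the
underlying studies never state their aggregate definition, and single
linkage on the hydrophobic moiety is the choice that makes "micelle"
coincide with "shared hydrophobic core". Unwrapping walks a spanning tree
of the linkage graph, shifting each molecule by lattice vectors to its
minimum image relative to its parent; geometry downstream always uses
unwrapped coordinates. An aggregate spanning more than half the box in
every dimension cannot be unwrapped unambiguously and is flagged.

Lineage tracking links aggregates across frames by greedy maximum member
overlap with ties broken toward the lower lineage id (deterministic); two
lineages mapping onto one aggregate record a merge event.

## Synthetic data: what it emulates, and what it does not

The generators replace the MD engine for testing. They reproduce the
*structural* assumptions of the analyses — not dynamics, energetics or
kinetics:

* **Micelles** anchor one AD per Fibonacci-sphere direction: ring beads at
  the core–shell interface (0.95·R), dendron heads fanned outward in
  shells, and tails curving through the core. Tail bead radial positions
  follow the volume-uniform quantiles of the core shape (ball quantiles
  R·q^(1/3) for spheres, disc quantiles for the cylindrical section of
  rods), so the pooled hydrophobic beads carry the second moment of a
  filled core and the √(5/3)·Rg estimator recovers the target radius — the
  construction is designed against the estimator it must satisfy, which is
  the generator's contract. Each chain bends in its tangent plane exactly
  enough to give the requested ring-to-tip tail length (n_tail·d_tail,
  default spacing 0.35 nm), clamped to what the core admits; the realized
  value is recorded in the frame's `micelle` attribute and is what recovery
  tests compare against. Scaling the core radius against the tail length
  tunes the interdigitation regime (I_d ≈ 0.9–1.5 for the systems studied).
* **Rods** are spherocylinders (straight section plus hemispherical caps,
  molecules distributed by surface area), which the gyration-tensor
  anisotropy flags at κ² well above 0.2.
* **Complexes** place the duplex at the box centre and micelles at
  requested COM distances around its waist; clashes under 0.3 nm are
  relaxed by small COM-preserving displacements, and infeasible requests
  (e.g. distance 0) are rejected rather than forced.
* **Solvent** is a jittered cubic lattice at the bulk CG water density
  (8.34 beads/nm³, one bead per four waters, spacing 0.4925 nm), with
  150 mM NaCl pairs (0.0903 pairs/nm³) plus exact counterions; generated
  systems are electroneutral to the integer, always.
* **Fusion trajectories** are scripted: COM distance stepping 9 → 6
  (plateau) → 2 (plateau) → merged, each micelle carrying a condensed
  chloride shell that co-moves with it over a sparse static solvent
  lattice (1.0 nm spacing — a fixture-scale solvent, not bulk density).
  The geometry alone then reproduces the canonical ordering: shared
  counterions appear while the heads are still ~1 nm apart, hydrophobic
  contacts only once the cores touch. Per-frame Gaussian noise
  (σ = 0.05 nm) exercises the estimators without breaking cluster
  identity.

Passing tests on these fixtures therefore demonstrates that the
*measurement layer* is correct (estimators recover known constructions;
counters match brute-force enumeration), not that real AD systems behave
this way — the generators have no thermodynamics, their solvent does not
respond to the solute, and their "dynamics" are schedules.

## Problem sizes and numerical choices

The test and analysis workloads are deliberately desk-scale: micelles of
2–60 ADs, complexes of up to 82 ADs around one duplex, fusion trajectories
of 60 frames, solvated boxes up to ~1,700 nm³, SASA at 240–480 sphere
points. These sizes keep every property suite comfortably within a few
minutes on one core while leaving all estimators in the regime where their
conventions (√(5/3)·Rg, uniform-disc cylinder radii) are meaningful.
Degenerate inputs are handled explicitly: single-molecule aggregates are
reported degenerate rather than given sphere geometry; empty species give
zero counts with a warning, not errors; non-positive cutoffs, overlapping
selections and infeasible placements are rejected with messages.

## Known limitations

* The head-tree bead counts per generation are a modelling convention;
  analyses that depend only on amine counts and the
  hydrophilic/hydrophobic split (everything here) are insensitive to it,
  but exported topologies are not force-field-accurate beyond that.
* Published mean interdigitation for 18C systems (~1.5) is not reproducible
  from the printed per-row radii (l₀/R of those rows gives ~1.3–1.4); the
  implemented formula is kept and the discrepancy noted rather than
  absorbed into the estimator.
* The curated reference tables carry a `consistent` flag; rows whose
  printed inputs contradict their own printed derived values are excluded
  from regression checks (four geometry rows, one amine row).
* SASA treats the aggregate as isolated (no periodic images); aggregates
  near half the box size should be analysed in larger boxes.
* No energies, no free-energy or CMC estimation, no transfection-efficiency
  claims: contact and coverage statistics are structural proxies only.
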