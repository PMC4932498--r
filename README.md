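# dendrimicelle

Coarse-grained modelling and self-assembly analysis of amphiphilic
PAMAM dendrimer (AD) / siRNA systems in R.

Amphiphilic dendrimers couple a low-generation hydrophilic PAMAM dendron
(G0, G1 or G2, carrying 2, 4 or 8 protonated terminal amines) to a single
hydrophobic alkyl tail (13, 15 or 18 carbons). In solution they self-assemble
into micelles whose size and shape control how well they condense and protect
siRNA — the property that makes some of these molecules effective gene-silencing
vectors and others not. This package provides, for structural and
computational chemists working on such carriers:

- **Topology builders** (`build_ad_topology()`, `build_sirna_topology()`,
  `apply_elastic_network()`): MARTINI-style bead models of the nine AD
  variants and of a 20 base-pair siRNA duplex with dTdT overhangs (one Qa
  phosphate, one P1 ribose and 2–3 base beads per nucleotide; all bead pairs
  within 0.7 nm restrained by a 1500 kJ mol⁻¹ nm⁻² elastic network), with
  ITP/GRO/PDB export.
- **Synthetic configuration generators** (`generate_micelle()`,
  `generate_complex()`, `solvate_and_neutralize()`,
  `generate_fusion_trajectory()`): seeded, deterministic micelles, siRNA
  complexes, 150 mM NaCl solvent and scripted two-micelle fusion events that
  stand in for MD trajectories during testing and method development.
- **Micelle metrics** (`micelle_geometry()`, `packing_and_shape()`,
  `derived_indices()`): radii of gyration, core/micelle radii
  (R = √(5/3)·Rg), and the Israelachvili packing framework

  P = v₀ / (a·l₀),  V = (4/3)πR³,  A = 4πR²,  R = 3V/A,

  with shape classes P ≤ 0.33 (sphere), 0.33–0.50 (cylinder), ≈0.50
  (bilayer); interdigitation I_d = l₀/R, surface charge density
  σ_m = e·N_agg/S_m, area per amine and the N/P ratio.
- **Interaction profiling** (`sasa()`, `count_contacts()`,
  `solvation_counts()`, `rdf_per_basepair()`, `com_distance_series()`,
  `amine_binding_stats()`): Shrake–Rupley solvent-accessible surface area,
  minimum-image contact counting at 0.75 nm, solvation shells at 0.65 nm,
  per-base-pair radial distribution maps and per-micelle amine-binding
  statistics.
- **Aggregation analysis** (`detect_aggregates()`, `track_aggregates()`,
  `fusion_profile()`): single-linkage clustering on hydrophobic beads under
  periodic boundaries, lineage tracking with merge events, and fusion
  observables (COM distance, shared chloride/water, contact types).

## Worked example

Build a 19-AD G2-18C micelle, detect it, and measure it:

```r
library(dendrimicelle)
spec <- ad_spec(2, 18)
fr   <- generate_micelle(spec, 19, core_radius_target = 1.1, seed = 7)
agg  <- detect_aggregates(fr, cutoff = 0.6)[[1]]
micelle_geometry(fr, agg, spec)
#> micelle N=19: R_m=2.31 nm, R_core=1.12 nm, l0=1.51 nm, P=0.25 (sphere)
derived_indices(micelle_geometry(fr, agg, spec), spec)$I_d
#> [1] 1.35
```

The micelle is recovered with its aggregation number exact, the core radius
within 2 % of the 1.1 nm target, a packing parameter of 0.25 — safely in the
spherical branch — and tails interdigitated (I_d > 1), as expected for an
18-carbon tail on a ~1.1 nm core.

The numbered scripts under `analysis/` run the full study: topology building
(`01`), synthetic system generation (`02`), micelle characterization against
the curated reference tables (`03`), siRNA-interaction profiling (`04`) and
fusion-event analysis (`05`). Each writes its tables under `results/`.
For example:

```sh
$ Rscript analysis/03_micelle_analysis.R
packing regression: 28/28 self-consistent rows within 0.015 (max dev 0.0149)
G0 rod interdigitation l0/R = 1.7/1.5 = 1.1
19-AD G2-18C micelle: area per amine 0.35 nm^2, sigma_m 2.85 e/nm^2
N/P of the bound G2-18C micelles: (13+19+24+26)/40 = 2.05 (~2:1)
...
```

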