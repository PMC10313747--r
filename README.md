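# sietraj

Trajectory analysis for receptor–ligand binding studies: solvated
interaction energy (SIE) scoring, geometric interaction criteria, and
two-dimensional free-energy landscapes of a gating receptor.

The motivating system is the wasp-venom phospholipase A₁ (Ves a 1 from
*Vespa affinis*), whose T83–E93 and G251–C261 loops act as a gate over the
catalytic pocket: their centroid separation populates a *closed* basin near
19 Å and an *open* basin near 22 Å. Candidate inhibitors docked into the
pocket are ranked by an end-point binding free energy computed over the
equilibrated tail of an MD trajectory. The package is for computational
chemists and structural bioinformaticians who have such trajectories (from
any engine) and want a tested, scriptable analysis layer.

## What it computes

* **Structural metrics** — Kabsch superposition, per-frame RMSD,
  per-residue RMSF about the time-average structure, loop
  centroid-distance series, open/close classification (boundary 20.5 Å,
  ties → open).
* **Solvent exposure** — Shrake–Rupley SASA (probe 1.4 Å, 960-point
  deterministic lattice) and the per-frame summed SASA of receptor
  residues within 5.0 Å of the ligand.
* **Interactions** — atom contacts (min distance ≤ 3.50 Å, heavy atoms),
  geometric hydrogen bonds (D–A ≤ 3.50 Å and D–H⋯A angle ≥ 150.00°, both
  inclusive), occupancy percentages over the analysis window, and
  per-residue interaction maps.
* **Energetics** — the SIE estimate

  ΔG_bind = α (E_vdW + γΔSA + E_ele + G_RF) + C,  α = 0.105,
  γ = 0.013 kcal mol⁻¹ Å⁻², C = −2.89 kcal/mol,

  on 100 evenly spaced snapshots from the last 10% of the run, with a
  Still-type generalized-Born reaction field (ε_in 2.25 / ε_out 78.5);
  plus a per-residue decomposition whose pairwise parts sum exactly to the
  intermolecular totals, with key residues flagged below −1.00 kcal/mol.
* **Free-energy landscape** — Boltzmann inversion
  ΔG(x, y) = −k_B T ln g(x, y)/g_max over (loop distance, loop RMSD) with
  0.10 Å bins at 310 K, minimum set to zero, basin detection, and
  per-frame gate labels.
* **Synthetic data** — seeded generators for a toy gating complex with
  scripted ground truth (basin means, H-bond occupancies, contact counts,
  fluctuation amplitudes), used by the test suite and usable as fixtures.

Inputs are plain text: PDB (single- or multi-model), multi-frame XYZ, and
a per-atom parameter TSV (charges, Lennard-Jones parameters, vdW and Born
radii), so the pipeline is engine-agnostic.

## Worked example

Everything below runs from scratch in a few seconds — the synthetic
generator stands in for a real trajectory:

```r
library(sietraj)

cx  <- make_toy_complex(n_residues = 50, seed = 1)
tr  <- simulate_gate_trajectory(cx, gate_params(n_frames = 6000, seed = 11))
tr  <- script_ligand_interactions(tr,
         ligand_script_params(occupancies = c(0.7, 0.4), seed = 12))
meta <- attr(cx$topology, "toy_meta")   # loop ranges "19-29", "31-41"

fel <- fel_pipeline(tr, meta$loopA_range, meta$loopB_range)
fel$basins
#>   x_center y_center     depth
#> 1    18.95     1.75 0.0000000
#> 2    21.75     0.45 0.1454905
table(fel$labels)
#> close  open
#>  3070  2930
```

The two basins sit at the generator's 19/22 Å gate separations and the
depth gap (0.15 kcal/mol) reflects their near-equal occupancy. Scoring
and decomposition over the equilibrated tail:

```r
sie <- sie_from_trajectory(tr, window = tail_window(tr), n_snapshots = 20,
                           sasa = sasa_params(n_sphere_points = 240))
sie
#> SIE binding free energy: -2.18 +/- 0.83 kcal/mol (20 snapshots)

dec <- per_residue_decomposition(tr, window = tail_window(tr),
                                 n_snapshots = 20,
                                 sasa = sasa_params(n_sphere_points = 240))
key_residues(dec)[, c("resno", "resname", "total")]
#>    resno resname     total
#> 18    18     SER -5.272192
#> 30    30     THR -3.566083

p1 <- meta$pairs[[1]]   # scripted serine donor -> ligand acceptor
hbond_occupancy(tr, p1$donor, p1$acceptor, window = tail_window(tr))
#> [1] 68.33333
```

The two flagged key residues are exactly the scripted hydrogen-bond
partners (the serine-like donor and the backbone acceptor), and the
recovered occupancy matches the 70% scripting target. Rescoring a
published component table through the combiner:

```r
tab <- sie_reference_components()
head(cbind(tab[, c("ligand", "run")],
           dg = round(sie_combine(tab$e_vdw, tab$e_ele, tab$g_rf, tab$cavity), 3),
           reported = tab$dg_reported), 4)
#>         ligand run      dg reported
#> 1         DMPC   1  -9.505    -9.49
#> 2         DMPC   2  -7.755    -7.74
#> 3         DMPC   3  -9.356    -9.34
#> 4 voxilaprevir   1 -10.174   -10.16
```

## Command line

A thin wrapper over the same functions ships in `inst/scripts/sietraj`:

```sh
Rscript inst/scripts/sietraj all --config run.yaml --seed 1 --out-dir out/
```

Subcommands: `simulate rmsd rmsf sasa contacts hbonds map sie decompose
fel all`. Each stage writes a CSV named after itself plus a run manifest;
configuration errors exit 2 (naming the offending key), data errors
exit 1. All outputs are byte-reproducible for a fixed config and seed.

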