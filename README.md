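# cgstack

Coarse-grained (CG) model parametrization by Boltzmann inversion of bonded
distributions, iterative refinement against a built-in Langevin engine, and
structural analysis of stacked molecular aggregates.

## Who this is for

Planar aromatic molecules — protoporphyrin IX (PpIX) is the motivating case —
stack face to face into rod-like, near-crystalline aggregates, and
amphiphilic additives can disrupt those stacks by adsorbing on their
surface, intercalating between the planes, or forming co-existing clusters.
`cgstack` is for modellers who want to (a) parametrize a CG model of such
molecules from an atomistic trajectory and (b) quantify aggregation and
additive placement in multi-molecule configurations, with every stage
testable against synthetic data of known ground truth.

## The methods at the core

**Harmonic Boltzmann inversion.** An internal coordinate with Gaussian
equilibrium marginal (mean μ, variance σ²) at temperature T is governed by
U(x) = ½k(x − μ)² with

    k = kB·T / σ²

(`fit_bond_harmonic`, `fit_angle_harmonic`; angles invert the variance in
rad²). Bonded distributions come from mapping an atomistic trajectory onto
beads (`map_trajectory`) and measuring every declared term
(`measure_bond_series`, `measure_angle_series`, `summarize_distribution`).

**Iterative refinement.** `refine_parameters` simulates the CG model with a
BAOAB Langevin integrator (`run_dynamics`; friction 0 is exactly velocity
Verlet), measures its bonded distributions, and applies the damped
moment-matching update

    r0 ← r0 + d·(μ_target − μ_cg),   k ← k·(σ²_cg / σ²_target)^d

until every term's base-2 Jensen–Shannon divergence to its target drops
below an explicit threshold (default 0.02 bits).

**Aggregation analysis.** `find_clusters` (single linkage on minimum
inter-site distances), `cluster_shape` (gyration eigenvalues, asphericity,
relative shape anisotropy κ² — 1 for rods, 0 for spheres), `stack_analysis`
(plane normals, inter-plane separations, rotation registration between
stacked neighbors), `classify_rotation` (bins {0, 90, 180, 270, other};
only 90/270 are permitted registrations), and `classify_placement`
(intercalated / surface / co_cluster / free per additive).

**Synthetic generators.** `gen_bonded_trajectory` (Gaussian bonded
marginals with known truth), `gen_stack_scene` and `gen_aggregate_scene`
(stacks and aggregates with controlled geometry), which close the loop with
the analysis functions exactly at zero jitter.

## Worked example

Parametrize a toy three-bead molecule from a synthetic "atomistic"
trajectory, then analyse a stacked scene:

```r
library(cgstack)

cfg  <- load_mapping_config(system.file("extdata", "toy_mapping.yaml",
                                        package = "cgstack"))
traj <- gen_bonded_trajectory(cfg$cg_topology, cfg$ground_truth,
                              n_frames = 50000, seed = 1)
bonded_summary_table(traj, cfg$cg_topology)
#>    term  kind        mean     variance     n
#> 1   1-2  bond   0.4699512 4.045226e-04 50000
#> 2   2-3  bond   0.3699504 2.233882e-04 50000
#> 3 1-2-3 angle 130.0256868 6.379456e+01 50000

ff <- fit_force_field(traj, cfg$cg_topology, thermo_state(310.15))
cat(export_parameters(ff, cfg$cg_topology, format = "itp"))
#> [ bonds ]
#> ;  i    j funct         b0         kb
#>    1    2     1     0.4700     6374.7
#>    2    3     1     0.3700    11543.7
#>
#> [ angles ]
#> ;  i    j    k funct        th0        cth
#>    1    2    3     2    130.026     132.70
```

The fitted `kb = 6374.7 kJ mol⁻¹ nm⁻²` is the Boltzmann inversion of the
measured variance; the closed form kB·310.15/0.02² = 6446.8 for the
generator's σ = 0.02 nm agrees to within this sample's 1% variance noise.
Stacking analysis on a jittered four-molecule stack built with rotations
90°, 270°, 90°:

```r
scene <- gen_stack_scene(4, spacing = 0.4, rotation_sequence = c(90, 270, 90),
                         jitter_sigma = 0.01, seed = 1)
geom <- stack_analysis(scene)
cbind(geom$pairs, classify_rotation(geom$pairs$rotation_deg, 10)[, c("bin", "permitted")])
#>   i j separation rotation_deg bin permitted
#> 1 2 1  0.3935952     92.24815  90      TRUE
#> 2 3 2  0.3968972    265.91150 270      TRUE
#> 3 4 3  0.4025656     93.85167  90      TRUE
```

Each neighboring pair is recovered at its constructed spacing (0.4 nm) and
rotation; 90/270 registrations are the permitted stacking pattern. Additive
placement in a 20-stacker rod with 4 intercalated additives:

```r
sc <- gen_aggregate_scene(20, 4, "intercalate", "rod", seed = 1)
classify_placement(sc)
#>   molecule      species        label
#> 1       21 additive:C14 intercalated
#> 2       22 additive:C14 intercalated
#> 3       23 additive:C14 intercalated
#> 4       24 additive:C14 intercalated
```

## Command line

A thin Rscript front end lives at `inst/cli/cgstack` (installed under
`system.file("cli", "cgstack", package = "cgstack")`), with subcommands
`map`, `stats`, `fit`, `simulate`, `refine`, `clusters`, `stacks` and
`synth`. Every run prints a `# key=value` header with all effective
parameters, defaults and seeds. Example:

```sh
cgstack synth stack --n 4 --spacing 0.4 --rotations 90,270,90 --seed 1 -o scene.pdb
cgstack stacks scene.pdb
```

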