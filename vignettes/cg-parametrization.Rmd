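---
title: "Coarse-grained parametrization and stacking analysis with cgstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained parametrization and stacking analysis with cgstack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgstack)
```

## The problem

Planar aromatic molecules such as protoporphyrin IX (PpIX) stack face to
face into rod-like, near-crystalline aggregates. Aggregation quenches the
photophysics that makes such molecules useful, and amphiphilic additives
(for instance alkylated chelators) can disrupt the stacks — by adsorbing on
the aggregate surface, by intercalating between the stacked planes, or by
forming separate co-existing clusters. Studying this computationally needs
two ingredients that `cgstack` provides:

1. **Coarse-grained (CG) model parametrization.** Groups of atoms are mapped
   onto beads; the bond-length and bond-angle distributions of the mapped
   atomistic trajectory define harmonic CG potentials by Boltzmann
   inversion; the CG model is then simulated and its parameters refined
   until its bonded distributions match the atomistic targets.
2. **Aggregation analysis.** Given a multi-molecule configuration ("scene"),
   detect clusters, quantify their shape (rod versus sphere), measure the
   stacking geometry including the rotation registration between
   neighboring planes, and classify where additives sit relative to the
   stacks.

All quantities use nm, ps, amu, kJ/mol and Kelvin — a consistent unit system
in which accelerations need no conversion factor (1 kJ mol⁻¹ nm⁻¹ / amu =
1 nm ps⁻²). Angles are degrees at every interface and radians only inside
force and inversion arithmetic, matching the ITP convention of equilibrium
angles in degrees with force constants in kJ mol⁻¹ rad⁻². All indices are
1-based: R is a 1-based language, and the ITP export convention coincides
with it, so no index translation exists anywhere in the package.

## Boltzmann inversion of bonded distributions

If an internal coordinate `x` (a bond length, or an angle) has a Gaussian
equilibrium marginal with mean `mu` and variance `s2` at temperature `T`,
it is distributed as if governed by the harmonic potential

    U(x) = 1/2 * k * (x - mu)^2,    k = kB * T / s2.

`fit_bond_harmonic()` and `fit_angle_harmonic()` apply exactly this
inversion to measured distributions (`summarize_distribution()` of the
series from `measure_bond_series()` / `measure_angle_series()`). Choices
worth knowing:

- **Unbiased variance.** The (n−1) estimator is used; on the small synthetic
  fixtures used in tests the difference from the population estimator is
  visible.
- **Angle units.** The equilibrium is reported in degrees, the variance is
  converted to rad² before the inversion.
- **Jacobian correction.** An angle sampled in Cartesian space carries a
  sin θ volume element. `jacobian_correct = TRUE` reweights samples by
  1/sin θ before computing moments. It is **off by default**: the
  parametrization loop matches CG moments to target moments measured the
  same way, so the bias cancels identically; the flag exists to make the
  choice explicit and testable (it is exactly symmetric about 90°, which
  the tests exploit).
- **kB is a fixed constant** (0.0083144621 kJ mol⁻¹ K⁻¹), not a parameter —
  configurable constants are a classic source of silent unit drift.

The default temperature is 310.15 K (37 °C), the condition the simulated
systems are studied at.

## Trajectory mapping

`map_frame()`/`map_trajectory()` project atomistic coordinates onto beads as
mass-weighted means (default) or unweighted means (`weighting =
"geometric"`). Which of the two a published model used is often unstated;
both are supported and the choice is recorded in the mapping config. Under
periodic boundaries every bead's members are first unwrapped to the image
nearest the bead's first member atom, so molecules straddling the box edge
do not produce beads in the box interior. Velocities are not mapped:
distribution matching uses positions only.

Mapping schemes are declarative YAML (`load_mapping_config()`): atoms,
beads with member atoms, bond terms and angle terms, all by name. The only
silent default is `weighting: mass`; any unknown atom, duplicate bead or
undefined bead in a term is a named error. One YAML 1.1 pitfall is handled
explicitly: bare `N`/`Y` parse as booleans, so element symbols N and Y (and
single-letter config keys) should be quoted; unquoted `element: N` falls
back to the name-derived element rather than failing.

## The dynamics engine

`run_dynamics()` integrates the CG model with the BAOAB splitting of
Langevin dynamics. With friction `gamma = 0` the O-step is the identity and
the scheme reduces *exactly* to velocity Verlet (NVE); this is a tested
identity, giving the engine a clean two-regime contract:

- **NVE** (`friction = 0`): total energy conserved to better than 1e-4
  relative over 1e5 steps at the 0.001 ps reference timestep.
- **Canonical** (`friction > 0`): time-averaged kinetic temperature within
  2% of the target and harmonic-bond variances matching kB·T/k.

The published simulation protocol this engine stands in for used a
v-rescale thermostat with pressure coupling. A barostat is deliberately
out of scope (refinement simulates one molecule in vacuum or a fixed box),
and BAOAB replaces v-rescale because the contract the pipeline needs —
correct canonical sampling of bonded marginals — is what BAOAB provides
with a small, testable implementation.

Other engine conventions:

- Forces: harmonic bonds and angles with the standard three-body gradient;
  Lennard-Jones 12-6 pairs truncated (unshifted) at the 1.1 nm default
  cutoff. The potential-shift modifier of the reference protocol is a
  simulation-engine detail irrelevant to bonded-distribution tests, so the
  unshifted choice is documented rather than imitated. Analytic forces are
  validated against central-difference gradients to 1e-6 relative.
- Beads joined by a bond or angle term are LJ-excluded (the standard 1-2
  and 1-3 exclusion).
- The nonbonded pair list is a plain O(N²) Verlet list with a 0.3 nm skin,
  refreshed every 20 steps by default (the reference protocol's update
  interval). At the molecule counts this package works at, cell lists
  would be complexity without benefit.
- Initial velocities are Maxwell-Boltzmann at the run temperature; the
  integrator uses R's RNG seeded from `engine_config$seed`, so identical
  seed + config gives bitwise-identical trajectories, and the caller's RNG
  state is restored afterwards.
- The kinetic temperature diagnostic removes the centre-of-mass velocity
  and divides by Ndof = 3N − 3, and the same convention is used inside the
  engine's temperature average.

## The refinement loop

`refine_parameters()` implements iterative parametrization: simulate the CG
model, measure its bonded distributions, compare to targets, adjust,
repeat. Two design decisions define it:

**Moment matching, not histogram inversion.** For harmonic terms the mean
and variance are sufficient statistics, so the update

    r0 <- r0 + damping * (mu_target - mu_cg)
    k  <- k * (var_cg / var_target)^damping

is the natural damped fixed-point iteration; full iterative Boltzmann
inversion of histograms would add noise sensitivity without adding
expressive power. The variance ratio is unitless, so the same update serves
bonds and angles. Damping defaults to 0.5 to prevent oscillation at short
sampling runs.

**An explicit convergence measure.** "Sufficient agreement" between
distributions is quantified as the base-2 Jensen-Shannon divergence (JSD)
of the two sample histograms, rebinned onto a shared edge set and compared
as probability mass per bin (hence invariant to the shared bin width). The
default threshold is 0.02 bits per term — an explicit, reported knob, not a
reconstruction of any published value. The loop stops **without** applying
a further update on the passing iteration, so `final_force_field` is
exactly the parameter set whose divergences were verified; the convergence
flag therefore agrees with the recorded history by construction. Iteration
`i` runs with seed `base_seed + i`: independent noise per iteration,
reproducible overall.

Two finite-sample properties of the JSD shaped the defaults:

- The plug-in JSD estimate between two *equal* distributions is biased
  upward by about `(B − 1)/(4 ln 2) * (1/N1 + 1/N2)` for `B` shared bins —
  more bins are not better. The divergence rebinning therefore defaults to
  60 bins (while `summarize_distribution()` keeps 100 bins for reporting).
- For Gaussians, a JSD of 0.02 bits corresponds to a mean offset of about
  0.33 σ or a variance ratio of about 1.4. The threshold alone therefore
  binds loosely on the force constant; it is the *mean* mismatch that keeps
  the loop iterating, halving all parameter errors each round under
  damping 0.5.

The second point dictates the design of the self-consistency benchmark used
in the tests and the acceptance script: targets are generated by the engine
under a known force field whose bond/angle widths are chosen so that the
initial +10% equilibrium offset equals 12 target σ (σ = 3.9 and 2.7 pm for
the bonds, 1.0° for the angle — deliberately stiff terms). The divergence
then crosses the 0.02 threshold only at the seventh iteration, by which
time the ×2 force-constant error has contracted to about 1%, comfortably
inside the 5% (k) and 1% (r0) recovery tolerances that the tests assert
across five seeds. Target runs use 3e6 steps and refinement runs 1.2e6
steps per iteration (saving every 20), sized so that the variance
estimator's sampling noise (about 1% per run) stays well below those
tolerances. These problem sizes are the package's own benchmark design,
verified against the JSD geometry before implementation.

## Aggregation and stacking analyses

- **Clusters** (`find_clusters()`): single-linkage connected components; two
  molecules are linked iff their minimum inter-site distance
  (minimum-image under PBC) is below `contact_cutoff` (default 0.6 nm, a
  typical CG bead contact — no published criterion exists to reconstruct).
- **Shape** (`cluster_shape()`): gyration-tensor eigenvalues
  λ1 ≥ λ2 ≥ λ3, asphericity λ1 − (λ2 + λ3)/2, and relative shape
  anisotropy κ² = 1 − 3(λ1λ2 + λ2λ3 + λ3λ1)/(λ1 + λ2 + λ3)², exactly 1 for
  a line (rod) and 0 for spherical symmetry. Degenerate inputs (single or
  fully coincident sites) return all metrics 0 by convention.
- **Stacking** (`stack_analysis()`): each stacker's plane normal is the
  smallest-eigenvalue eigenvector of its core-site covariance (a collinear
  core is a "degenerate plane" error). Normal signs are co-oriented by
  propagating the first stacker's orientation, preventing spurious 180°
  flips. Neighbor pairs require normal alignment within 30° (default) and a
  projected centroid separation inside [0.3, 0.7] nm (default); the
  rotation angle between two stacked molecules is the signed,
  counter-clockwise angle between their reference axes projected into the
  pair's mean plane, mapped to [0, 360). Counter-clockwise about the
  co-oriented normal is an arbitrary but fixed handedness; 90 and 270 stay
  distinct bins, as the stacking pattern demands.
- **Rotation classification** (`classify_rotation()`): nearest of
  {0, 90, 180, 270} by circular distance within a tolerance (default 15°,
  must be < 45° or bins overlap), else `other`. `permitted` is `TRUE`
  exactly for 90 and 270 — the rotational registrations the stacked planar
  cores admit; 0 and 180 are sterically forbidden.
- **Placement** (`classify_placement()`): per additive, the first matching
  label of **intercalated** (a site strictly between two consecutive stack
  planes and within `lateral_radius` — default 1.5× the stackers' mean core
  radius of gyration — of the pair axis), **surface** (same single-linkage
  cluster as a stacker *and* a site within `contact_cutoff` of a stacker
  site), **co_cluster** (member of an additive-only cluster of ≥ 2 whose
  sites come within `attachment_factor × contact_cutoff` of a stacker site,
  default factor 2), else **free**. Labels are mutually exclusive and
  exhaustive by construction. The separate attachment radius is a
  deliberate design choice: an additive cluster whose gap to the stackers
  is *below* the contact cutoff necessarily has a member in direct surface
  contact, so "co-existing cluster" is only a coherent category at
  arm's-length attachment.

## Synthetic data: what it emulates and what it does not

The generators produce inputs with exactly the statistical structure the
pipeline assumes, with known ground truth:

- `gen_bonded_trajectory()` builds frames by sequential placement over the
  bond tree: bond lengths and declared angles from their Gaussians,
  torsions and unconstrained directions uniform (the maximum-entropy
  choice; no dihedral potentials are fitted anywhere in the package).
  σ = 0 reproduces the exact means in every frame.
- `gen_stack_scene()` stacks a square-planar 4-site template (ring radius
  0.25 nm, reference axis site 3 → site 1) along +z with controlled
  spacings and per-step rotations plus optional Gaussian jitter. The
  template is a deliberate geometric abstraction of a planar tetrapyrrole
  core — atom-level coordinates of the real molecule are not part of this
  package's inputs.
- `gen_aggregate_scene()` arranges stackers as one rod (alternating 90/270
  rotations) or an isotropic lattice-ball cluster, then places additives so
  that `classify_placement()` provably returns the requested label:
  intercalated additives sit on the stack axis in a gap widened to 0.55 nm
  (still inside the neighbor-pair separation window); surface additives are
  walked radially inward until they sit ~0.36 nm from the nearest stacker
  site; scattered additives stay beyond 3 contact cutoffs; co-clustered
  additives form a packed block held at ~0.87 nm (between the contact and
  attachment radii). `split_stacks = TRUE` instead widens intercalated gaps
  to 1.2 nm, severing the stacker cluster at each intercalation point —
  the geometry used for the disruption trend (mean stacker cluster size
  strictly decreasing as the intercalated fraction grows from 0% through
  25% to 50%).
- Compositions scale: the simulated systems' 100:14 stacker:additive ratio
  is reproduced at reduced counts (e.g. 50:7) without any change in the
  generators.

Passing the closure tests shows the *analysis conventions are mutually
consistent and correctly implemented* — it does not show that real
atomistic trajectories satisfy the Gaussian-marginal assumption, that real
aggregates are single-linkage-separable at 0.6 nm, or that thermal disorder
in a real stack is as benign as Gaussian jitter. Those are modelling
assumptions the user must judge against their own data.

## Numerical choices and degenerate inputs

- Histograms clamp out-of-range samples into the edge bins so counts always
  sum to the sample count; constant samples get a hair-width bin range.
- Angle forces guard sin θ ≥ 1e-8 at collinearity; angle measurement errors
  on zero-length arms name the offending frame.
- The gyration κ² is clipped into [0, 1] against rounding.
- PDB/XYZ are Angstrom on disk (nm internally); XYZ writes 6 decimals
  (1e-6 Å round trip), PDB 3 decimals (1e-3 Å), GRO 3 decimals in nm. The
  structured JSON force-field serialization writes 17 significant digits
  and round-trips doubles bit-exactly; ITP round-trips at its printed
  precision. Only orthorhombic boxes are supported; triclinic input is an
  explicit unsupported-feature error.
- Scene PDB files encode species in residue names (`STK` for stackers);
  4-site `STK` residues are re-annotated with the square-planar core on
  reading, so written scenes round-trip through the full analysis.

## Known limitations

- Harmonic bonded terms only: no dihedrals, no tabulated potentials, no
  nonbonded (LJ) *derivation* — pair parameters are user input, as the
  reference workflow takes them from an existing CG force field.
- No electrostatics, constraints, or pressure coupling; the engine is a
  desk-scale sampling tool, not a production MD code.
- Single-linkage clustering is chaining-prone by construction; that is the
  intended definition here, not an oversight.
- The co_cluster attachment radius and the contact cutoff are conventions;
  results should be reported together with these values (the CLI logs them
  in every run header).
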