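---
title: "Integrative NMR + density refinement: models, parameters and design choices"
author: "nmrem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative NMR + density refinement: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrem)
```

## The problem

Solid-state (magic-angle-spinning) NMR of a protein bound to a large,
insoluble assembly — here the motif is a kinesin motor domain decorating
polymerized microtubules — yields carbon–carbon cross-peaks that encode
through-space proximities, and chemical-shift-derived backbone torsion
restraints. On their own, a few restraints per residue at modest precision
underdetermine a fold; a medium-resolution (6–8 Å) cryo-EM density map on its
own resolves the envelope but not atomic detail. Combining the two is what
this package implements: cross-peaks become flat-bottom distance restraints;
a single chain is refined by restrained simulated annealing inside a density
envelope; the refined chain is rigid-body docked at every copy position of
the map; the multi-copy assembly is refined jointly under a
non-crystallographic-symmetry (NCS) similarity restraint; and a mobile
segment (the neck linker, residues 321–349 in the motivating system) is
refined locally with the core held rigid.

## Restraint model

Each assigned cross-peak contributes one restraint. Unambiguous assignments
are classified by sequence separation (intra, sequential |i−j| = 1, medium
1 < |i−j| < 5, long |i−j| ≥ 5). Bounds follow the standard calibration for
this class of data: intra-residue 1.5–6.5 Å (target 4.0 ± 2.5 Å),
inter-residue 2.0–7.2 Å (4.6 ± 2.6 Å). Peaks with more than 5 candidate
assignments are discarded. Ambiguous restraints are scored on the effective
distance $d_\mathrm{eff} = (\sum_p d_p^{-6})^{-1/6}$ over candidate pairs —
the standard NOE convention in which any one satisfied candidate satisfies
the restraint — inside a flat-bottom quadratic:

$$E = k\,[\max(0, d_\mathrm{eff}-U)^2 + \max(0, L-d_\mathrm{eff})^2].$$

Two conventions required a decision:

* **Medium-range interval.** Source tables print both `1 < |i-j| < 5` and
  `1 <= |i-j| < 5`; the strict form (|i−j| ∈ {2,3,4}) is adopted so that
  sequential and medium-range are disjoint and the category counts add up.
* **Mixed ambiguity.** When an ambiguous restraint mixes intra- and
  inter-residue candidates it takes the looser inter-residue bounds, since
  ambiguity must never over-restrain.

Two further bookkeeping notes: the published restraint table's internal
arithmetic (937 + 209 unambiguous + 193 ambiguous = 1339) is what the
accounting functions reproduce; the accompanying text figure of 1140
unambiguous disagrees with the table's 1146 and the package reports what it
computes. Likewise 1339/349 rounds to 3.84 restraints per residue, not the
printed 3.85; the computed value is reported, not "fixed".

## Energy terms and units

All terms are evaluated in compiled code with analytic gradients
(kcal mol⁻¹, Å; dihedral force constants per rad², converted from degrees at
the interface):

* covalent geometry — harmonic bonds, angles, impropers about a compact
  Engh–Huber-style ideal-value table (k_bond 600 kcal mol⁻¹ Å⁻²,
  k_angle 120, k_improper 100 kcal mol⁻¹ rad⁻²);
* distance restraints — flat-bottom quadratic above, force constant ramped
  2 → 30 kcal mol⁻¹ Å⁻² across cooling;
* torsion restraints — quadratic beyond a per-restraint tolerance
  (default ±20° when a table omits it, the typical uncertainty of
  shift-derived predictions), 10 kcal mol⁻¹ rad⁻² at high temperature and
  200 during cooling;
* density term — $E = k(1-\mathrm{CC})$ with $k = 50$ kcal mol⁻¹, where CC
  is the real-space Pearson correlation between the simulated density of
  backbone (N, C′, Cα, O) atoms and the target map over the target-derived
  mask (voxels above 10% of the map maximum). Restricting the term to
  backbone atoms leaves sidechain orientations to the NMR restraints. The
  exact cross-correlation probability-distribution potential of the
  reference refinement engine lives in cited prior work; $k(1-\mathrm{CC})$
  is a deliberate, documented surrogate with the same fixed point.
* NCS similarity — for every subunit pair, optimal superposition followed by
  a quadratic penalty on the RMSD excess over a 1.0 Å tolerance
  (k = 100 kcal mol⁻¹ Å⁻²; the reference protocol states only the 1 Å
  allowance, so the force constant is a package choice);
* a soft-sphere repulsion below 2.0 Å between non-bonded atoms (keeps chains
  from passing through themselves; the package has no Lennard-Jones or
  electrostatics, which are out of scope);
* an optional weak radius-of-gyration restraint standing in for the
  gyration-volume term, automatically disabled whenever a map term is
  present (the two conflict).

The statistical torsion-angle potential and the hydrogen-bond database term
of the reference protocol are replaced by the harmonic dihedral restraints
and (optionally) a simple backbone hydrogen-bond distance term; both
replacements are simplifications, documented here, not re-implementations.

Simulated density uses per-atom isotropic Gaussians with
σ = resolution/(π√2), a common EM convention, truncated at 4.5σ (>99.8% of
the 3-D mass); the in-dynamics density term truncates at 3σ for speed, which
perturbs CC by well under 10⁻³.

## Dynamics and annealing

Dynamics are Cartesian velocity-Verlet with a velocity-rescaling thermostat
— a deliberate simplification of the reference engine's
internal-coordinate/torsion-angle dynamics that is easier to verify and
adequate at desk scale. Masses are standard element masses. The timestep
starts at 1 fs and is self-adjusted: any step that changes the total energy
by more than 2% of its magnitude halves the timestep (floor 0.1 fs), and
after 100 well-behaved steps it relaxes back. The 2% rule is a declared
surrogate — the reference protocol says only that the step was adjusted "to
ensure conservation of energy".

When one rigid group is present (the localized-refinement stage), the
thermostat measures and rescales the free atoms only; the rigid body starts
at rest and moves under forces alone, with light velocity damping. This is a
deliberate stabilization: at 3000 K a thermally driven rigid core would
tumble out of its density envelope, an artifact the real engine's
internal-coordinate dynamics does not share. Runs whose adaptive timestep
cannot rescue a diverging step are marked failed, excluded from batches and
counted; if every run for one subunit fails, the localized-refinement stage
keeps that subunit's joint-refinement pose and warns.

The default schedule is the published one: two 3000 K stages (10 ps or
10,000 steps, whichever first), then cooling 3000 → 25 K in 25 K steps
(120 stages) with 0.4 ps per stage; distance-restraint k ramps linearly in
stage index from 2 to 30 kcal mol⁻¹ Å⁻² (linear because the source says only
"ramped"); the dihedral k switches from 10 to 200 at the start of cooling;
the map k stays 50. A decrement that does not divide the cooling range is a
configuration error by default; `build_schedule(..., strict = FALSE)`
instead appends a terminal stage at the end temperature (used by the
scaled-down acceptance run, whose prescribed 125 K decrement does not divide
2975 K). Each annealing run ends with a gradient minimization (L-BFGS-B on
the compiled energy; the reference names Powell minimization — any descent
scheme satisfying the same contract).

Batches of annealed structures are sorted by total energy (including the map
term; the source does not separate selection criteria per stage) and
"lowest-energy structure" always means index 1.

## Docking

Multi-position docking scans a deterministic super-Fibonacci rotation set
(seedless, quasi-uniform in SO(3), default 2000 orientations — tests and the
acceptance run use a few hundred, which suffices at toy scale) over a
translation grid, scoring poses by mean interpolated density at Cα atoms; the
best candidates are polished by BFGS ascent on the real-space CC with the
gradient chained analytically through the Gaussian density model, then
thinned by non-maximum suppression at one radius of gyration. Fits are
ranked by *highest* CC; the source's phrase "lowest cross-correlation
values" is treated as a wording slip, since the same sentence selects best
fits.

## The synthetic world

Real inputs (deposited restraints, a deposited map) cannot ship with a
desk-scale package, so every stage is exercised against generated fixtures
whose ground truth is known:

* **Toy folds** are ideal-geometry chains with canonical per-element
  torsions (helix −60/−45, strand −120/+120). "Loop" elements are 4-residue
  reversing turns (φ/ψ = (−120,120), (−120,120), (60,45), (−140,160)),
  chosen once by construction so flanking elements pack against each other —
  without packing the fixture has almost no long-range restraints and the
  fold is underdetermined. Pseudo-sidechains are 0–3 carbons (CB, CG, CD) at
  idealized positions; a deterministic pass over staggered χ rotamers
  relieves steric clashes without touching the (exactly ideal) covalent
  geometry.
* **Labeling schemes** are simplified visibility masks: `uniform_13C` sees
  all carbons; `glucose_16` (1,6-¹³C-glucose) the carbonyl and terminal
  sidechain carbon; `glucose_2` (2-¹³C-glucose) Cα and CG. True glucose
  isotopomer statistics are far richer; the masks only reproduce the
  *spectral thinning* that makes long-range contacts detectable.
* **Peak lists** contain one peak per visible carbon pair inside the
  detection cutoff (recommended ≤ 7.2 Å, the inter-residue upper bound) and
  above the class lower bound; a seeded fraction receives decoy assignments
  (only on inter-residue peaks, decoys ≥ 3.5 Å and checked against the r⁻⁶
  sum) so that the master guarantee holds: the true coordinates satisfy
  every emitted restraint.
* **Lattices** place copies on a helical lattice (radial offset, rise,
  twist) with a clash check, and simulate the blurred map.
* **The standard fixture** ("fixture A", master seed 7) is a 30-residue
  helix-loop-helix with glucose_16 labeling, 7.2 Å cutoff, 15% ambiguity, a
  4-copy lattice and an 8 Å map; the text inputs ship in
  `inst/extdata/fixture_a/` and regenerate bit-exactly from the seed (the
  map being binary is regenerated rather than shipped). With these stated
  parameters the packed fold emits about 6 restraints per residue — the
  density is emergent, not a tuned dial.

What a green synthetic test establishes: that the machinery — restraint
conversion, energies and gradients, annealing, docking, NCS coupling,
validation — does what its contract says on data whose answer is known. What
it does not establish: performance on real spectra (peak overlap,
assignment errors, inhomogeneous linewidths), real maps (noise, anisotropy,
masking artifacts), or real protein energetics (no physical force field).

Start models for recovery experiments are torsion-jittered refolds of the
truth (σ ≈ 10°, ~3–6 Å backbone RMSD) — the synthetic analogue of seeding
from a medium-resolution structure of the same protein, which is exactly how
the real protocol is seeded. From a fully extended chain the toy restraint
set does not determine the fold, as expected at ~6 restraints per residue
with ±2.6 Å tolerances.

## Validation statistics

`validate()` computes, per conformer and pooled across the ensemble
(mean ± s.d.; the source's pooling is unstated, per-conformer-then-pool is
this package's documented choice): the mean magnitude of distance violations
over restraints exceeding their bounds (the table row "distance restraints
≥ 7.2 Å" is read as exactly this quantity), the dihedral analogue beyond
tolerance, maximum violations, RMS deviations from idealized geometry, and
average pairwise RMSD for the backbone (N, Cα, C′) and heavy-atom
selections, each pair superposed before measuring. The deposited reference
ensemble reports both a 22-member backbone statistic (0.89 ± 0.09 Å) and a
"10 lowest-energy conformer" figure (1.2 ± 0.1 Å); both selections are
computable here and neither is silently preferred.

## Degenerate inputs and numerical edges

Superposition requires ≥ 3 non-collinear atoms; dihedral gradients return
zero on collinear frames rather than NaN; a structure entirely outside a map
raises an out-of-map error (partial overlap is allowed and scored on the
overlapping mask); Pearson CC is undefined on constant masked values and
errors; restraints whose atoms cannot be resolved name the offending
restraint. Annealing runs that diverge below the timestep floor are marked
failed, excluded from batches, and counted.

## Known limitations

Single rigid group per system (sufficient for the neck-linker stage);
hydrogens, protonation states, alternate locations and insertion codes are
out of scope; no FFT-accelerated docking (the coarse scan is O(rotations ×
grid)); the NCS gradient uses the envelope theorem at the superposition
optimum, which is exact only at the optimum the superposition itself
computes; mmCIF support covers the `atom_site` loop only. The 22-subunit,
349-residue scale of the motivating study is far beyond desk scale — the
package runs the same protocol on its synthetic analogues and on any inputs
of comparable size a user supplies.
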