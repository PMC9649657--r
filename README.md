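# nmrem

Integrative structure refinement from solid-state NMR distance restraints
and medium-resolution cryo-EM density maps, at desk scale.

For proteins bound to large insoluble assemblies (the motivating system is a
kinesin motor domain on polymerized microtubules), magic-angle-spinning NMR
yields sparse carbon–carbon proximity restraints and backbone torsion
restraints, while cryo-EM yields a 6–8 Å density envelope. Neither source
alone determines an atomic model; together they do. `nmrem` implements the
full protocol for users who want to run, test, or teach it on their own
restraint tables, coordinate files and maps:

1. **Restraint preparation** — assigned cross-peaks (TSV) become classified,
   non-redundant, possibly ambiguous distance restraints with flat-bottom
   bounds (intra-residue 1.5–6.5 Å, inter-residue 2.0–7.2 Å; ≤ 5-fold
   ambiguity; r⁻⁶ sum averaging), plus peak-list comparison between two
   sample states (chemical-shift perturbation and intensity ratios).
2. **Single-chain refinement** — restrained simulated annealing
   (velocity-Verlet, velocity-rescaling thermostat, adaptive timestep;
   default schedule: two 3000 K stages then cooling 3000 → 25 K by 25 K,
   distance-k ramped 2 → 30 kcal mol⁻¹ Å⁻², dihedral k 10/200, map k 50)
   inside a low-resolution envelope.
3. **Docking** — multi-position rigid-body search of the chain in the
   experimental map (deterministic rotation set, translation scan,
   gradient-refined real-space cross-correlation, non-maximum suppression).
4. **Joint refinement** — the docked copies refined together under
   per-subunit restraints, the density term, and a non-crystallographic
   symmetry restraint penalizing pairwise subunit RMSD beyond 1 Å.
5. **Localized refinement** — a mobile segment (e.g. the neck linker)
   re-annealed per subunit with the core held as one rigid body, then
   realigned and locally refitted to the map.
6. **Validation** — restraint-violation statistics, idealized-geometry
   deviations, and pairwise ensemble RMSD, in the layout of an NMR
   structure-statistics table; plus an alternative-start convergence check.

A first-class synthetic-data module generates toy folds, labeling-scheme
filtered peak lists, torsion tables, multi-copy lattices and blurred maps
with known ground truth, so the entire pipeline is testable offline.

The energy core (restraint terms, density cross-correlation with analytic
gradients, NCS, the integrator) is compiled (Rcpp/RcppArmadillo). File
formats: PDB and minimal mmCIF for coordinates, MRC2014 for maps, TSV for
peaks/restraints/torsions/placements, JSON for configuration.

## Worked example

Generate the standard synthetic fixture (30-residue helix–loop–helix,
sparse-labeling peak list, 4-copy lattice with an 8 Å map), then run the
pipeline from a deliberately imperfect start model:

```r
library(nmrem)

fx <- fixture_a()                      # master seed 7
summarize_restraints(fx$restraints, fx$torsions, n_residues = 30)
#> Distance restraints
#>   Unambiguous              163
#>     Intra-residue           10
#>     Inter-residue          153
#>       Sequential            40
#>       Medium-range          88
#>       Long-range (sc-sc)    25 (3)
#>   Ambiguous                 17
#>   Total                    180
#>   Restraints/residue      6.00
#> Torsion restraints: phi 29, psi 29, total 58

# a torsion-jittered refold stands in for a medium-resolution start model
set.seed(1)
truth <- fx$fold$structure
start <- new_structure(
  nmrem:::build_chain_atoms(truth$sequence,
                            fx$fold$truth$phi + rnorm(30, 0, 10),
                            fx$fold$truth$psi + rnorm(30, 0, 10)),
  sequence = truth$sequence)
superpose(truth, start, "name N,CA,C")$rmsd
#> [1] 2.24          # a few A from the truth

sched <- build_schedule(list(high_duration_ps = 1, high_max_steps = 1000,
                             decrement = 125, per_T_duration_ps = 0.4),
                        strict = FALSE)       # reduced, desk-scale schedule
cfg <- pipeline_config(n_structures_stage1 = 3, n_structures_stage3 = 1,
                       n_per_subunit = 1, n_subunits = 4,
                       free_range = c(23, 30), schedule = sched,
                       rotation_samples = 300, seed = 1)

out <- run_pipeline(start, fx$restraints, fx$torsions, fx$lattice$map,
                    extra_restraints = fx$linker_restraints, config = cfg)

superpose(truth, out$stage1$structure, "name N,CA,C")$rmsd
#> [1] 1.4             # refined single chain, backbone RMSD to the truth
max(pairwise_ensemble_rmsd(out$stage3$assembly, "backbone")$matrix)
#> [1] 0.64            # NCS keeps the 4 subunits within the 1 A allowance
```

(Stochastic quantities: the printed numbers are one seed's output; other
seeds give similar values.) The full-size defaults
(`pipeline_config()` with 100/100/1000 structures, 22 subunits, the 120-stage
cooling schedule) reproduce the published protocol's shape and are practical
for overnight runs on real-scale inputs.

A thin command-line wrapper over the same functions ships in
`inst/scripts/run_pipeline.R` (subcommands `run`, `restraints`, `dock`,
`simulate`, `validate`).

## Acceptance script

`scripts/acceptance.R` regenerates the standard fixture, runs single-chain
annealing, docks the chain at the four lattice positions, performs the
scaled-down joint refinement with the NCS term (tolerance 1.0 Å, reduced
schedule), and reports the maximum pairwise backbone RMSD among the refined
subunits as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
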