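# Synthetic generators: determinism, labeling-scheme monotonicity, the master
# zero-energy guarantee, lattices, and second-state perturbation.

test_that("toy folds are deterministic with the requested torsions", {
  f1 <- make_toy_fold(10, "helix", seed = 3)
  f2 <- make_toy_fold(10, "helix", seed = 3)
  expect_identical(coords(f1$structure), coords(f2$structure))
  tor <- nmrem:::measure_torsions(f1$structure)
  expect_true(all(abs(tor$phi[-1] - (-60)) < 5))
  expect_equal(unname(geometry_deviations(f1$structure)), c(0, 0, 0),
               tolerance = 1e-6)
  expect_error(make_toy_fold(10, "helix-coil", seed = 1), "unknown")
  expect_error(make_toy_fold(3, "helix"), ">= 5")
})

test_that("peak simulation respects cutoff, visibility and self-consistency", {
  fx <- make_toy_fold(20, "helix-loop-helix", seed = 9)
  s <- fx$structure
  expect_equal(nrow(simulate_peaks(s, labeling_scheme("uniform_13C"),
                                   cutoff = 0, seed = 1)$peaks), 0)
  # visibility subsets imply peak subsets
  all_pk <- simulate_peaks(s, labeling_scheme("uniform_13C"), cutoff = 7.2,
                           seed = 1)$peaks
  g2 <- simulate_peaks(s, labeling_scheme("glucose_2"), cutoff = 7.2,
                       seed = 1)$peaks
  key <- function(p) paste(p$res_i, p$atom_i, p$res_j, p$atom_j)
  expect_true(all(key(g2) %in% key(all_pk)))
  expect_error(simulate_peaks(s, labeling_scheme("glucose_2",
                                                 visible = "XX"),
                              7.2), "no visible atoms")
  # the module's core guarantee: truth incurs zero restraint energy,
  # including ambiguous restraints and torsions
  pk <- simulate_peaks(s, labeling_scheme("uniform_13C"), cutoff = 7.2,
                       ambiguity_rate = 0.4, seed = 5)
  rs <- peaks_to_restraints(pk$peaks)
  expect_gt(sum(vapply(rs, function(r) r$category == "ambiguous", TRUE)), 0)
  expect_equal(distance_energy(s, rs, 30)$total, 0)
  tor <- simulate_torsions(s, tolerance = 20, noise = 0, seed = 5)
  expect_equal(dihedral_energy(s, tor, 200)$total, 0)
  # torsion bookkeeping: (n-1) phi and (n-1) psi for a single chain
  expect_equal(sum(tor$angle == "phi"), 19)
  expect_equal(sum(tor$angle == "psi"), 19)
  expect_identical(simulate_torsions(s, seed = 2),
                   simulate_torsions(s, seed = 2))
})

test_that("lattices reduce to single-copy maps and superpose linearly", {
  s <- make_toy_fold(10, "helix", seed = 2)$structure
  one <- make_lattice(s, n_copies = 1, resolution = 8, voxel = 2)
  solo <- simulate_map(one$assembly$subunits[[1]], 8, 2,
                       template = one$map)
  expect_equal(cross_correlation(one$map, solo), 1, tolerance = 1e-12)
  expect_equal(max(abs(solo$grid - one$map$grid)), 0, tolerance = 1e-9)
  # lattice map equals the sum of per-copy maps (linearity)
  lat <- make_lattice(s, n_copies = 3, spacing = 25, axial_rise = 18,
                      twist = 40, resolution = 8, voxel = 2)
  per_copy <- lapply(lat$assembly$subunits, function(u)
    simulate_map(u, 8, 2, template = lat$map))
  summed <- Reduce(`+`, lapply(per_copy, function(m) m$grid))
  expect_equal(cross_correlation(new_density_map(summed, 2, lat$map$origin,
                                                 8), lat$map), 1,
               tolerance = 1e-12)
  # clashing geometry is rejected with advice
  expect_error(make_lattice(s, n_copies = 2, spacing = 0, axial_rise = 0.5,
                            twist = 5, resolution = 8, voxel = 2),
               "clash")
})

test_that("state perturbation plants exactly the requested CSPs", {
  fx <- make_toy_fold(25, "helix-loop-helix", seed = 12)
  pk <- simulate_peaks(fx$structure, labeling_scheme("uniform_13C"),
                       cutoff = 6.5, seed = 12)$peaks
  # empty perturbation set: identical list
  same <- perturb_state(fx$structure, pk, integer(0))
  expect_identical(same$peaks, pk)
  # delta 0 and factor 1: flags all unchanged
  null_p <- perturb_state(fx$structure, pk, 5:8, shift_delta = 0,
                          intensity_factor = 1, seed = 2)
  cmp0 <- compare_states(pk, null_p$peaks, 0.1, 0.5)
  expect_true(all(cmp0$flag == "unchanged"))
  expect_error(perturb_state(fx$structure, pk, c(1, 99)), "outside")
})

test_that("fixture A regenerates its committed files bit-exactly", {
  dir <- tempfile()
  fx <- fixture_a(dir, include_binary = FALSE)
  shipped <- system.file("extdata", "fixture_a", package = "nmrem")
  expect_true(nzchar(shipped))
  for (f in c("peaks.tsv", "torsions.tsv", "truth.pdb", "truth.json")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(shipped, f)), label = f)
  }
  expect_equal(length(fx$restraints) / 30,
               jsonlite::fromJSON(file.path(shipped,
                                            "truth.json"))$n_restraints / 30)
  # the lattice map itself is regenerated deterministically
  fx2 <- fixture_a()
  expect_identical(fx$lattice$map$grid, fx2$lattice$map$grid)
})
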