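# Energy terms: values against hand-computed cases, flat-bottom behavior,
# ambiguity averaging, masking, additivity, and analytic-vs-numeric gradients.

test_that("flat-bottom distance restraints match hand arithmetic", {
  at <- data.frame(chain = "A", resi = c(1L, 2L), resn = "ALA",
                   atom = "CA", elem = "C", x = c(0, 5), y = 0, z = 0)
  s <- new_structure(at, topology = nmrem:::empty_topology())
  r <- restraints_from_pairs(data.frame(res_i = 1, atom_i = "CA",
                                        res_j = 2, atom_j = "CA"))
  # d = 5 inside [2, 7.2]: zero energy, zero gradient
  e <- distance_energy(s, r, k = 30)
  expect_equal(e$total, 0)
  expect_equal(max(abs(e$gradient)), 0)
  # d = upper + 0.5 at k = 30: E = 30 * 0.25 = 7.5
  coords(s) <- matrix(c(0, 0, 0, 7.7, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(distance_energy(s, r, k = 30)$total, 7.5, tolerance = 1e-10)
  # below the lower bound the penalty is quadratic in (L - d)
  coords(s) <- matrix(c(0, 0, 0, 1.0, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(distance_energy(s, r, k = 30)$total, 30 * 1.0^2,
               tolerance = 1e-10)
})

test_that("ambiguous restraints use r^-6 sum averaging", {
  at <- data.frame(chain = "A", resi = 1:4, resn = "ALA", atom = "CA",
                   elem = "C", x = c(0, 4, 10, 30), y = 0, z = 0)
  s <- new_structure(at, topology = nmrem:::empty_topology())
  # candidates: 1-2 at 4 A and 3-4 at 20 A
  r <- peaks_to_restraints(peak_row("e", 1, "CA", 2, "CA",
                                    alt = "3.CA-4.CA"))
  deff <- (4^-6 + 20^-6)^(-1 / 6)
  expect_equal(deff, 4, tolerance = 1e-3) # dominated by the short pair
  got <- nmrem:::eff_distances(s, r)
  expect_equal(got, deff, tolerance = 1e-10)
  expect_equal(distance_energy(s, r, 30)$total, 0) # 4 A inside bounds
})

test_that("dihedral restraints wrap and penalize beyond tolerance", {
  s <- tiny_fold(6, "helix")
  tor <- simulate_torsions(s, tolerance = 10, noise = 0, seed = 1)
  expect_equal(dihedral_energy(s, tor, 200)$total, 0)
  # target + 360 wraps to zero penalty
  tor2 <- tor
  tor2$target <- wrap_angle(tor2$target + 360)
  expect_equal(dihedral_energy(s, tor2, 200)$total, 0, tolerance = 1e-9)
  # |delta| - tol = 0.1 rad at k = 200 -> 2.0 kcal/mol
  tor3 <- tor[tor$angle == "phi" & tor$resi == 3, ]
  tor3$target <- wrap_angle(tor3$target - (10 + 0.1 * 180 / pi))
  expect_equal(dihedral_energy(s, tor3, 200)$total, 200 * 0.01,
               tolerance = 1e-6)
})

test_that("covalent energy is zero at ideal geometry and grows harmonically", {
  s <- tiny_fold(5)
  expect_equal(covalent_energy(s)$total, 0, tolerance = 1e-18)
  # stretching one bond monotonically increases the energy
  i <- s$topology$bonds$j[1]
  es <- sapply(c(0.02, 0.05, 0.1, 0.2), function(d) {
    p <- s
    X <- coords(p); X[i, 1] <- X[i, 1] + d
    coords(p) <- X
    covalent_energy(p)$total
  })
  expect_true(all(diff(es) > 0))
})

test_that("NCS energy penalizes only RMSD excess and ignores rigid motion", {
  s <- tiny_fold(8)
  a <- replicate_subunits(s, 2)
  expect_equal(ncs_energy(a, 1, 10)$total, 0)
  # pure rigid motion of one subunit: still zero
  coords(a$subunits[[2]]) <- sweep(coords(s) %*% t(random_rotation(2)), 2,
                                   c(12, 3, -5), `+`)
  expect_equal(ncs_energy(a, 1, 10)$total, 0, tolerance = 1e-9)
  # engineered pair RMSD of 1.5 with tol 1.0 at k = 10: E = 10 * 0.25
  n <- n_atoms(s)
  set.seed(6)
  d <- matrix(rnorm(3 * n), ncol = 3)
  d <- sweep(d, 2, colMeans(d)) # remove net translation
  # strip the rotational component by superposing the perturbed copy back
  b <- replicate_subunits(s, 2)
  coords(b$subunits[[2]]) <- coords(s) + d
  fit <- superpose(s, b$subunits[[2]], "heavy")
  coords(b$subunits[[2]]) <- coords(fit$transformed)
  resid <- coords(b$subunits[[2]]) - coords(s)
  rmsd0 <- sqrt(mean(rowSums(resid^2)))
  coords(b$subunits[[2]]) <- coords(s) + resid * (1.5 / rmsd0)
  got <- ncs_energy(b, tolerance = 1.0, k = 10)$total
  expect_equal(got, 10 * 0.25, tolerance = 0.02)
  expect_error(ncs_energy(replicate_subunits(s, 1)), "at least 2")
})

test_that("map energy vanishes at self-density and respects residue masks", {
  s <- tiny_fold(10)
  # target simulated from the same backbone selection: CC = 1, E = 0
  mp <- simulate_map(s, 8, 2, selection = "backbone")
  e <- map_energy(s, mp, k = 50, selection = "backbone")
  expect_equal(e$total, 0, tolerance = 5e-3)
  expect_true(all(abs(e$terms) <= 50 * 2 + 1e-9)) # E in [0, 2k]
  # masked residues contribute no gradient
  e2 <- map_energy(s, mp, k = 50, selection = "backbone",
                   residue_mask = 1:5)
  excluded <- which(s$atoms$resi > 5)
  expect_equal(max(abs(e2$gradient[excluded, ])), 0)
  sidechain <- which(!(s$atoms$atom %in% c("N", "CA", "C", "O")))
  expect_equal(max(abs(e$gradient[sidechain, ])), 0)
  # entirely outside the map: out-of-map error
  far <- s; coords(far) <- coords(s) + 500
  expect_error(map_energy(far, mp), "out-of-map")
})

test_that("total energy is additive and the gyration term yields to the map", {
  fx <- make_toy_fold(12, "helix", seed = 3)
  s <- fx$structure
  set.seed(4)
  coords(s) <- coords(s) + matrix(rnorm(3 * n_atoms(s), 0, 0.3), ncol = 3)
  pk <- simulate_peaks(fx$structure, labeling_scheme("uniform_13C"),
                       cutoff = 6.5, seed = 2)
  r <- peaks_to_restraints(pk$peaks)
  tor <- simulate_torsions(fx$structure, seed = 2)
  mp <- simulate_map(fx$structure, 8, 2)
  sys <- make_system(s, r, tor, mp)
  e <- total_energy(sys)
  expect_equal(e$total, sum(e$terms), tolerance = 1e-10)
  # all terms disabled -> zero
  off <- energy_config(k_bond = 0, k_angle = 0, k_improper = 0, k_dist = 0,
                       k_dih = 0, k_map = 0, k_ncs = 0, k_repel = 0)
  expect_equal(total_energy(make_system(s, r, tor, mp, off))$total, 0)
  # with a map present, the radius-of-gyration surrogate is forced off
  cfg <- energy_config(k_rgyr = 5)
  sys2 <- make_system(s, r, tor, mp, cfg)
  expect_null(sys2$spec$k_rgyr)
  # without a map it is active
  sys3 <- make_system(s, r, tor, NULL, cfg)
  expect_false(is.null(sys3$spec$k_rgyr))
})

test_that("every term's analytic gradient matches finite differences", {
  fx <- make_toy_fold(10, "helix-loop-strand", seed = 5)
  s <- fx$structure
  set.seed(8)
  X <- coords(s) + matrix(rnorm(3 * n_atoms(s), 0, 0.4), ncol = 3)
  pk <- simulate_peaks(fx$structure, labeling_scheme("uniform_13C"),
                       cutoff = 7.2, ambiguity_rate = 0.3, seed = 3)
  r <- peaks_to_restraints(pk$peaks)
  tor <- simulate_torsions(fx$structure, seed = 3)
  mp <- simulate_map(fx$structure, 8, 2)
  sys <- make_system(s, r, tor, mp,
                     energy_config(k_rgyr = 0, k_repel = 6, r_repel = 3))
  expect_lt(fd_gradient_error(X, sys$spec, n_checks = 25, seed = 1), 1e-3)
  # assembly with NCS
  a <- replicate_subunits(s, 3)
  set.seed(9)
  for (k in 2:3)
    coords(a$subunits[[k]]) <- coords(s) +
      matrix(rnorm(3 * n_atoms(s), 0, 0.6), ncol = 3)
  sysa <- make_system(a, r, tor, NULL,
                      energy_config(k_ncs = 50, tol_ncs = 0.2))
  Xa <- nmrem:::system_coords(sysa)
  expect_lt(fd_gradient_error(Xa, sysa$spec, n_checks = 25, seed = 2), 1e-3)
  # fuzz small random systems over covalent + restraints
  for (seed in 1:3) {
    fz <- make_toy_fold(6, "helix", seed = seed)
    set.seed(seed)
    Xf <- coords(fz$structure) +
      matrix(rnorm(3 * n_atoms(fz$structure), 0, 0.5), ncol = 3)
    sysf <- make_system(fz$structure,
                        peaks_to_restraints(simulate_peaks(
                          fz$structure, labeling_scheme("uniform_13C"),
                          cutoff = 6, seed = seed)$peaks),
                        simulate_torsions(fz$structure, seed = seed))
    expect_lt(fd_gradient_error(Xf, sysf$spec, n_checks = 15, seed = seed),
              1e-3)
  }
})

test_that("unresolvable restraint atoms are reported by restraint", {
  s <- tiny_fold(5)
  r <- restraints_from_pairs(data.frame(res_i = 2, atom_i = "CZ",
                                        res_j = 4, atom_j = "CA"))
  expect_error(distance_energy(s, r), "restraint 1")
})
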