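# Annealing schedules, velocity initialization, dynamics, minimization and
# batch runs.

test_that("the default schedule reproduces the published protocol", {
  sch <- build_schedule()
  st <- sch$stages
  cool <- st[st$phase == "cool", ]
  expect_equal(nrow(cool), 120) # (3000 - 25) / 25 + 1
  expect_equal(cool$temperature[1], 3000)
  expect_equal(cool$temperature[120], 25)
  expect_equal(cool$k_dist[1], 2)
  expect_equal(cool$k_dist[120], 30)
  high <- st[st$phase == "high", ]
  expect_equal(nrow(high), 2)
  expect_true(all(high$temperature == 3000))
  expect_true(all(high$k_dih == 10))
  expect_true(all(cool$k_dih == 200))
  expect_true(all(st$k_map == 50))
  expect_equal(sch$initial_timestep_fs, 1)
  expect_error(build_schedule(list(decrement = 123)), "divide")
  # non-strict mode appends the terminal stage instead
  relaxed <- build_schedule(list(decrement = 125), strict = FALSE)
  ct <- relaxed$stages$temperature[relaxed$stages$phase == "cool"]
  expect_equal(ct[length(ct)], 25)
})

test_that("Maxwell velocities are seeded, vanish at T=0, and equipartition", {
  s <- tiny_fold(8)
  v1 <- maxwell_velocities(s, 3000, seed = 4)
  v2 <- maxwell_velocities(s, 3000, seed = 4)
  expect_identical(v1, v2)
  expect_false(identical(v1, maxwell_velocities(s, 3000, seed = 5)))
  expect_equal(maxwell_velocities(s, 0, seed = 1),
               matrix(0, n_atoms(s), 3))
  # 10,000-atom equipartition check at 3000 K
  masses <- rep(12.011, 10000)
  v <- maxwell_velocities(masses, 3000, seed = 2)
  temp <- nmrem:::measured_temperature(v, masses)
  expect_lt(abs(temp - 3000), 150)
})

test_that("dynamics: free drift, oscillator energy conservation, determinism", {
  # zero-force system drifts linearly at constant potential
  at <- data.frame(chain = "A", resi = 1:2, resn = "ALA", atom = "CA",
                   elem = "C", x = c(0, 10), y = 0, z = 0)
  s <- new_structure(at, topology = nmrem:::empty_topology())
  sys <- make_system(s, config = energy_config(k_repel = 0))
  v0 <- matrix(c(1, 0, 0, 0, 2, 0), 2, 3, byrow = TRUE) # A/ps
  r <- dynamics_stage(sys, 300, duration_ps = 1, thermostat = FALSE,
                      velocities = v0)
  X1 <- nmrem:::system_coords(r$system)
  expect_equal(unname(X1[1, 1]), 1 * r$summary$duration_ps, tolerance = 1e-6)
  expect_equal(unname(X1[2, 2]), 2 * r$summary$duration_ps, tolerance = 1e-6)
  expect_equal(r$summary$epot, 0)
  # harmonic dimer: total energy conserved within 1% over 10 ps at 1 fs
  top <- list(bonds = data.frame(i = 1L, j = 2L, r0 = 1.53),
              angles = nmrem:::empty_topology()$angles,
              impropers = nmrem:::empty_topology()$impropers)
  dimer <- new_structure(data.frame(chain = "A", resi = c(1L, 1L),
                                    resn = "ALA", atom = c("CA", "CB"),
                                    elem = "C", x = c(0, 1.83), y = 0, z = 0),
                         topology = top)
  sysd <- make_system(dimer, config = energy_config(k_bond = 100,
                                                    k_repel = 0))
  e0 <- total_energy(sysd, gradient = FALSE)$total # 100 * 0.09
  rd <- dynamics_stage(sysd, 300, duration_ps = 10, thermostat = FALSE,
                       velocities = matrix(0, 2, 3))
  etot <- rd$summary$epot + rd$summary$ekin
  expect_lt(abs(etot - e0) / e0, 0.01)
  expect_equal(rd$summary$n_halvings, 0)
  # oscillator period matches the closed form: T = 2 pi sqrt(mu / (2 k conv))
  mu <- 12.011 / 2
  period_ps <- 2 * pi * sqrt(mu / (2 * 100 * 418.4))
  rhalf <- dynamics_stage(sysd, 300, duration_ps = period_ps / 2,
                          thermostat = FALSE, velocities = matrix(0, 2, 3))
  # after half a period the bond is compressed to r0 - 0.3
  Xh <- nmrem:::system_coords(rhalf$system)
  expect_equal(unname(abs(Xh[2, 1] - Xh[1, 1])), 1.53 - 0.3, tolerance = 0.02)
  # bitwise determinism under a fixed seed
  fx <- tiny_fold(6)
  sysf <- make_system(fx, config = energy_config())
  a <- dynamics_stage(sysf, 500, 0.2, seed = 3)
  b <- dynamics_stage(sysf, 500, 0.2, seed = 3)
  expect_identical(nmrem:::system_coords(a$system),
                   nmrem:::system_coords(b$system))
  expect_identical(a$summary, b$summary)
})

test_that("thermostatted stages hold the target temperature", {
  s <- make_toy_fold(60, "helix-loop-helix", seed = 2)$structure # > 300 atoms
  expect_gte(n_atoms(s), 300)
  sys <- make_system(s)
  r <- dynamics_stage(sys, 500, duration_ps = 0.4, seed = 1)
  expect_lt(abs(r$summary$temp_measured - 500) / 500, 0.1)
})

test_that("minimization descends to the quadratic minimum", {
  top <- list(bonds = data.frame(i = 1L, j = 2L, r0 = 1.53),
              angles = nmrem:::empty_topology()$angles,
              impropers = nmrem:::empty_topology()$impropers)
  dimer <- new_structure(data.frame(chain = "A", resi = c(1L, 1L),
                                    resn = "ALA", atom = c("CA", "CB"),
                                    elem = "C", x = c(0, 2.4), y = 0, z = 0),
                         topology = top)
  sys <- make_system(dimer, config = energy_config(k_repel = 0))
  m <- minimize(sys)
  X <- coords(m$structure)
  expect_equal(sqrt(sum((X[2, ] - X[1, ])^2)), 1.53, tolerance = 1e-3)
  expect_lte(m$energy$total, total_energy(sys, gradient = FALSE)$total)
  # a system already at its minimum stays put
  m2 <- minimize(m$system)
  expect_equal(coords(m2$structure), X, tolerance = 1e-4)
})

test_that("annealing relaxes restraint energy and is seed-deterministic", {
  fx <- make_toy_fold(12, "helix-loop-helix", seed = 4)
  pk <- simulate_peaks(fx$structure, labeling_scheme("uniform_13C"),
                       cutoff = 7.2, seed = 4)
  rs <- peaks_to_restraints(pk$peaks)
  tor <- simulate_torsions(fx$structure, seed = 4)
  # start from a deliberately wrong (extended) conformation
  ext <- nmrem:::build_chain_atoms(fx$structure$sequence, rep(-120, 12),
                                  rep(120, 12))
  s0 <- new_structure(ext, sequence = fx$structure$sequence)
  sys <- make_system(s0, rs, tor)
  e0 <- distance_energy(s0, rs, 30)$total + dihedral_energy(s0, tor,
                                                            200)$total
  sch <- test_schedule()
  run <- anneal(sys, sch, seed = 2)
  e1 <- distance_energy(run$structure, rs, 30)$total +
    dihedral_energy(run$structure, tor, 200)$total
  expect_lt(e1, 0.1 * e0) # >= 90% drop in restraint energy
  # same seed reproduces the trajectory summary bitwise
  run2 <- anneal(make_system(s0, rs, tor), sch, seed = 2)
  expect_identical(run$trajectory, run2$trajectory)
  expect_equal(coords(run$structure), coords(run2$structure))
  # different seeds give different conformers, both satisfying restraints
  run3 <- anneal(make_system(s0, rs, tor), sch, seed = 3)
  expect_gt(max(abs(coords(run3$structure) - coords(run$structure))), 1e-6)
  for (r in list(run, run3)) {
    d <- nmrem:::eff_distances(r$structure, rs)
    lo <- vapply(rs, `[[`, 0, "lower"); hi <- vapply(rs, `[[`, 0, "upper")
    expect_lt(max(pmax(0, d - hi, lo - d)), 0.5)
  }
  # an empty schedule reduces to plain minimization
  sch0 <- test_schedule()
  sch0$stages <- sch0$stages[0, ]
  just_min <- anneal(make_system(fx$structure, rs, tor), sch0, seed = 1)
  expect_equal(coords(just_min$structure), coords(fx$structure),
               tolerance = 0.05)
})

test_that("batch runs sort by energy and tolerate failures", {
  fx <- make_toy_fold(8, "helix", seed = 6)
  pk <- simulate_peaks(fx$structure, labeling_scheme("uniform_13C"),
                       cutoff = 6, seed = 6)
  rs <- peaks_to_restraints(pk$peaks)
  sys <- make_system(fx$structure, rs, simulate_torsions(fx$structure,
                                                         seed = 6))
  b <- run_batch(sys, test_schedule(0.2, 0.1), n_structures = 4,
                 base_seed = 10)
  en <- vapply(b, function(r) r$energy$total, 0)
  expect_true(all(diff(en) >= 0))
  expect_equal(attr(b, "n_failed"), 0)
  b1 <- run_batch(sys, test_schedule(0.2, 0.1), n_structures = 1,
                  base_seed = 10)
  expect_length(b1, 1)
  expect_equal(b1[[1]]$energy$total, b[[which(vapply(b, `[[`, 0, "seed") ==
                                                10)]]$energy$total)
})
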