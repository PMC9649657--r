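# Structure container, coordinate I/O, superposition, ensemble statistics,
# chain extension and assemblies.

test_that("PDB round-trip preserves atoms to file precision", {
  s <- tiny_fold(5, "helix")
  f <- tempfile(fileext = ".pdb")
  write_structure(s, f)
  r1 <- read_structure(f)
  f2 <- tempfile(fileext = ".pdb")
  write_structure(r1, f2)
  r2 <- read_structure(f2)
  expect_equal(r1$atoms$atom, s$atoms$atom)
  expect_equal(r1$atoms$resn, s$atoms$resn)
  expect_equal(coords(r1), coords(r2))
  expect_equal(coords(r1), round(coords(s), 3), tolerance = 1e-9)
})

test_that("multi-model PDB reads as an ensemble and mmCIF round-trips", {
  ens <- list(tiny_fold(5), tiny_fold(5))
  coords(ens[[2]]) <- coords(ens[[2]]) + 5
  f <- tempfile(fileext = ".pdb")
  write_structure(ens, f)
  back <- read_structure(f)
  expect_s3_class(back, "nmrem_ensemble")
  expect_length(back, 2)
  expect_equal(coords(back[[2]]) - coords(back[[1]]),
               matrix(5, n_atoms(ens[[1]]), 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  fc <- tempfile(fileext = ".cif")
  write_structure(ens[[1]], fc)
  rc <- read_structure(fc)
  expect_equal(rc$atoms$atom, ens[[1]]$atoms$atom)
  expect_equal(coords(rc), round(coords(ens[[1]]), 3), tolerance = 1e-9)
})

test_that("missing element columns are inferred from atom names", {
  s <- tiny_fold(5)
  f <- tempfile(fileext = ".pdb")
  write_structure(s, f)
  lines <- readLines(f)
  lines <- substr(lines, 1, 66) # drop segid + element columns
  writeLines(lines, f)
  r <- read_structure(f)
  expect_equal(r$atoms$elem, s$atoms$elem)
  # malformed coordinates are reported with the line number
  lines[3] <- sub("[0-9]\\.[0-9]{3}", "x.q42", lines[3])
  writeLines(lines, f)
  expect_error(read_structure(f), "line 3")
})

test_that("superposition satisfies the Kabsch contract", {
  s <- tiny_fold(8)
  expect_equal(superpose(s, s, "heavy")$rmsd, 0, tolerance = 1e-10)
  # pure rigid motion is recovered exactly
  R <- random_rotation(3)
  m <- s
  coords(m) <- sweep(coords(s) %*% t(R), 2, c(4, -2, 9), `+`)
  fit <- superpose(s, m, "heavy")
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # symmetry of the RMSD
  set.seed(5)
  m2 <- s
  coords(m2) <- coords(s) + matrix(rnorm(3 * n_atoms(s), 0, 0.7), ncol = 3)
  expect_equal(superpose(s, m2, "heavy")$rmsd,
               superpose(m2, s, "heavy")$rmsd, tolerance = 1e-6)
  expect_error(superpose(s, tiny_fold(9), "heavy"), "different atom counts")
})

test_that("Kabsch matches a brute-force quaternion-grid oracle", {
  set.seed(8)
  for (rep in 1:3) {
    A <- matrix(rnorm(30, 0, 3), 10, 3)
    B <- matrix(rnorm(30, 0, 3), 10, 3)
    fit <- nmrem:::kabsch_fit(A, B)
    # oracle: coarse quaternion grid + Nelder-Mead refinement over rotation
    # vectors, translation solved by centering
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    obj <- function(v) {
      R <- nmrem:::rotvec_to_matrix(v)
      sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
    }
    qs <- rotation_samples(600)
    vals <- apply(qs, 1, function(q)
      obj(nmrem:::matrix_to_rotvec(nmrem:::quat_to_matrix(q))))
    v0 <- nmrem:::matrix_to_rotvec(nmrem:::quat_to_matrix(qs[which.min(vals), ]))
    best <- optim(v0, obj, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))$value
    expect_equal(fit$rmsd, best, tolerance = 1e-4)
    expect_lte(fit$rmsd, best + 1e-6) # global minimum contract
  }
})

test_that("pairwise ensemble RMSD behaves and is rigid-motion invariant", {
  s <- tiny_fold(8)
  ens <- list(s, s, s)
  r <- pairwise_ensemble_rmsd(ens, "backbone")
  expect_equal(r$mean, 0, tolerance = 1e-9)
  expect_equal(r$sd, 0, tolerance = 1e-9)
  set.seed(2)
  m <- s; coords(m) <- coords(s) + matrix(rnorm(3 * n_atoms(s), 0, 0.5),
                                          ncol = 3)
  two <- pairwise_ensemble_rmsd(list(s, m), "backbone")
  expect_equal(two$mean, superpose(s, m, "name N,CA,C")$rmsd,
               tolerance = 1e-9)
  expect_equal(two$sd, 0)
  # moving one member rigidly changes nothing
  m2 <- m
  coords(m2) <- sweep(coords(m) %*% t(random_rotation(9)), 2, c(30, 1, -8),
                      `+`)
  expect_equal(pairwise_ensemble_rmsd(list(s, m2), "backbone")$mean,
               two$mean, tolerance = 1e-6)
  bad <- m; bad$atoms$atom[4] <- "ZZ"
  expect_error(pairwise_ensemble_rmsd(list(s, bad)), "mismatch")
})

test_that("geometry deviations: ideal zero, hand case, rigid invariance", {
  s <- tiny_fold(6)
  expect_equal(unname(geometry_deviations(s)), c(0, 0, 0), tolerance = 1e-9)
  # 4 ideal bonds, one stretched by 0.02: rmsd = sqrt(0.0004/4) = 0.01
  at <- data.frame(chain = "A", resi = 1L, resn = "ALA",
                   atom = paste0("X", 1:5), elem = "C",
                   x = c(0, 1.5, 3.0, 4.5, 6.02), y = 0, z = 0)
  top <- list(bonds = data.frame(i = 1:4, j = 2:5, r0 = 1.5),
              angles = data.frame(i = integer(0), j = integer(0),
                                  k = integer(0), th0 = numeric(0)),
              impropers = data.frame(i = integer(0), j = integer(0),
                                     k = integer(0), l = integer(0),
                                     phi0 = numeric(0)))
  toy <- new_structure(at, topology = top)
  expect_equal(unname(geometry_deviations(toy)["bond"]), 0.01,
               tolerance = 1e-12)
  # rigid motion leaves the deviations unchanged
  set.seed(3)
  p <- s; coords(p) <- coords(s) + matrix(rnorm(3 * n_atoms(s), 0, 0.05),
                                          ncol = 3)
  g1 <- geometry_deviations(p)
  coords(p) <- sweep(coords(p) %*% t(random_rotation(4)), 2, c(7, -3, 2), `+`)
  expect_equal(geometry_deviations(p), g1, tolerance = 1e-8)
  # empty topology is an error
  e <- new_structure(at, topology = nmrem:::empty_topology())
  expect_error(geometry_deviations(e), "topology")
})

test_that("chain extension appends ideal-geometry residues without clashes", {
  full <- make_toy_fold(20, "strand", seed = 2)$structure
  # nothing missing: untouched
  expect_equal(coords(extend_chain(full, full$sequence)), coords(full))
  # C-terminal truncation: rebuild to full length with exact ideal geometry
  trunc <- full
  keep <- trunc$atoms$resi <= 14
  trunc <- new_structure(trunc$atoms[keep, ],
                         sequence = substr(full$sequence, 1, 14))
  ext <- extend_chain(trunc, full$sequence)
  expect_equal(n_residues(ext), 20)
  added <- new_structure(ext$atoms[ext$atoms$resi >= 15, ],
                         sequence = substr(full$sequence, 15, 20))
  expect_equal(unname(geometry_deviations(added)), c(0, 0, 0),
               tolerance = 1e-8)
  X <- coords(ext)
  dmin <- nmrem:::min_cross_distance(X, which(ext$atoms$resi >= 15),
                                     ext$atoms$resi)
  expect_gte(dmin, 1.5)
  # a helix end whose raw extension grazes the fold is relaxed instead:
  # clash-free with near-ideal geometry
  hfull <- make_toy_fold(20, "helix", seed = 2)$structure
  htrunc <- new_structure(hfull$atoms[hfull$atoms$resi <= 14, ],
                          sequence = substr(hfull$sequence, 1, 14))
  hext <- extend_chain(htrunc, hfull$sequence)
  expect_gte(nmrem:::min_cross_distance(coords(hext),
                                        which(hext$atoms$resi >= 15),
                                        hext$atoms$resi), 1.5)
  expect_lt(max(geometry_deviations(hext)), 0.5)
  # internal single-residue gap: peptide connectivity restored
  gap <- new_structure(full$atoms[full$atoms$resi != 10, ],
                       sequence = paste0(substr(full$sequence, 1, 9),
                                         substr(full$sequence, 11, 20)))
  gap$atoms$resi[gap$atoms$resi > 10] <- gap$atoms$resi[gap$atoms$resi > 10]
  closed <- extend_chain(new_structure(full$atoms[full$atoms$resi != 10, ],
                                       sequence = NULL), full$sequence)
  at <- closed$atoms
  C10 <- unlist(at[at$resi == 10 & at$atom == "C", c("x", "y", "z")])
  N11 <- unlist(at[at$resi == 11 & at$atom == "N", c("x", "y", "z")])
  C9 <- unlist(at[at$resi == 9 & at$atom == "C", c("x", "y", "z")])
  N10 <- unlist(at[at$resi == 10 & at$atom == "N", c("x", "y", "z")])
  expect_equal(sqrt(sum((C10 - N11)^2)), 1.33, tolerance = 0.05)
  expect_equal(sqrt(sum((C9 - N10)^2)), 1.33, tolerance = 0.05)
  # sequence mismatch names the position
  wrong <- paste0(substr(full$sequence, 1, 4), "W",
                  substr(full$sequence, 6, 20))
  expect_error(extend_chain(full, wrong), "position 5")
})

test_that("subunit replication deep-copies with shared template", {
  s <- tiny_fold(5)
  a1 <- replicate_subunits(s, 1)
  expect_equal(coords(a1$subunits[[1]]), coords(s))
  a <- replicate_subunits(s, 22)
  expect_length(a$subunits, 22)
  expect_equal(a$segment_ids, LETTERS[1:22])
  expect_true(all(vapply(a$subunits, n_atoms, 0) == n_atoms(s)))
  # mutating one subunit leaves the others alone
  coords(a$subunits[[3]]) <- coords(a$subunits[[3]]) + 10
  expect_equal(coords(a$subunits[[2]]), coords(s))
  expect_error(replicate_subunits(s, 2, c("A", "A")), "duplicate")
})

test_that("the selection mini-language resolves tokens", {
  s <- tiny_fold(10)
  expect_equal(length(select_atoms(s, "name CA")), 10)
  expect_equal(length(select_atoms(s, "backbone")), 40)
  expect_equal(length(select_atoms(s, "heavy")), n_atoms(s))
  r <- select_atoms(s, "backbone resi 3-5")
  expect_equal(sort(unique(s$atoms$resi[r])), 3:5)
  expect_equal(length(r), 12)
  expect_error(select_atoms(s, "chains A"), "unknown token")
})
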