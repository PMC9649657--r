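# Map simulation, cross-correlation, MRC I/O and rigid-body docking.

test_that("simulated maps peak at atoms, scale linearly, integrate correctly", {
  one <- matrix(c(5.3, 4.1, 6.2), 1, 3)
  mp <- simulate_map(one, resolution = 6, voxel = 1.5)
  peak <- which(mp$grid == max(mp$grid), arr.ind = TRUE)[1, ]
  vox_pos <- mp$origin + (peak - 1) * mp$voxel
  expect_lt(sqrt(sum((vox_pos - one)^2)), sqrt(3) * mp$voxel)
  # doubling atoms (two at the same spot) doubles integrated density
  two <- rbind(one, one)
  mp2 <- simulate_map(two, resolution = 6, voxel = 1.5)
  expect_equal(sum(mp2$grid), 2 * sum(mp$grid), tolerance = 1e-9)
  # integral ~ n * (2 pi sigma^2)^(3/2) / voxel^3 (Gaussian closed form)
  s <- tiny_fold(8)
  mp3 <- simulate_map(s, resolution = 8, voxel = 2)
  sigma <- 8 / (pi * sqrt(2))
  expect_equal(sum(mp3$grid) * 2^3,
               n_atoms(s) * (2 * pi * sigma^2)^(3 / 2), tolerance = 0.01)
  expect_error(simulate_map(s, resolution = 2, voxel = 2), "twice the voxel")
})

test_that("cross-correlation bounds, self-correlation and null behavior", {
  s <- tiny_fold(10)
  mp <- simulate_map(s, 8, 2)
  expect_equal(cross_correlation(mp, mp), 1, tolerance = 1e-12)
  neg <- new_density_map(-mp$grid, mp$voxel, mp$origin, mp$resolution)
  expect_equal(cross_correlation(mp, neg,
                                 mask = abs(mp$grid) > 0.1 * max(mp$grid)),
               -1, tolerance = 1e-12)
  # CC(simulate(S), simulate(S)) = 1 through the structure-vs-map path
  expect_equal(cross_correlation(s, mp), 1, tolerance = 1e-3)
  # independently seeded noise maps decorrelate
  set.seed(1); a <- array(rnorm(64^3), c(64, 64, 64))
  set.seed(2); b <- array(rnorm(64^3), c(64, 64, 64))
  cc <- cross_correlation(new_density_map(a, 1), new_density_map(b, 1),
                          mask = array(TRUE, dim(a)))
  expect_lt(abs(cc), 0.1)
})

test_that("MRC round-trip is voxel-identical and honors the origin", {
  s <- tiny_fold(6)
  mp <- simulate_map(s, 8, 2)
  f <- tempfile(fileext = ".mrc")
  write_mrc(mp, f)
  r1 <- read_mrc(f, resolution = 8)
  expect_equal(dim(r1$grid), dim(mp$grid))
  expect_equal(max(abs(r1$grid - mp$grid)), 0, tolerance = 1e-6)
  expect_equal(r1$voxel, mp$voxel, tolerance = 1e-5)
  expect_equal(r1$origin, mp$origin, tolerance = 1e-4)
  f2 <- tempfile(fileext = ".mrc")
  write_mrc(r1, f2)
  r2 <- read_mrc(f2)
  expect_identical(as.numeric(r1$grid), as.numeric(r2$grid))
  expect_error(suppressWarnings(read_mrc(tempfile())))
  # a corrupt mode flag is rejected
  bytes <- readBin(f, "raw", file.size(f))
  bytes[13:16] <- as.raw(c(9, 0, 0, 0))
  writeBin(bytes, f2)
  expect_error(read_mrc(f2), "mode")
})

test_that("non-canonical axis order reads into identical real-space content", {
  s <- tiny_fold(6)
  mp <- simulate_map(s, 8, 2)
  f <- tempfile(fileext = ".mrc")
  write_mrc(mp, f)
  # build a permuted file by hand: data stored z-fastest with mapc/r/s = 3,2,1
  g <- aperm(mp$grid, c(3, 2, 1))
  d <- dim(mp$grid)
  con <- file(f, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d[c(3, 2, 1)]); wi(2); wi(c(0, 0, 0)); wi(d[c(3, 2, 1)])
  wf(d[c(3, 2, 1)] * mp$voxel); wf(c(90, 90, 90))
  wi(c(3, 2, 1))
  wf(c(min(g), max(g), mean(g))); wi(c(1, 0)); wi(rep(0, 25))
  wf(mp$origin[c(1, 2, 3)])
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(sd(as.numeric(g))); wi(0); writeBin(raw(800), con)
  wf(as.numeric(g))
  close(con)
  r <- read_mrc(f)
  expect_equal(dim(r$grid), d)
  expect_equal(max(abs(r$grid - mp$grid)), 0, tolerance = 1e-6)
})

test_that("docking recovers a planted single copy and local_fit ascends", {
  s <- tiny_fold(14, "helix-loop-helix")
  mp <- simulate_map(s, 8, 2)
  pl <- dock_positions(s, mp, n_positions = 1, rotation_samples = 300)
  expect_length(pl, 1)
  top <- pl[[1]]
  expect_lt(sqrt(sum(top$translation^2)), 2)
  expect_lt(nmrem:::rotation_angle_between(top$rotation, diag(3)), 5)
  expect_gt(top$score, 0.98)
  # local_fit: fixed point at the optimum
  ident <- nmrem:::new_placement(diag(3), c(0, 0, 0))
  ref <- local_fit(s, mp, ident)
  expect_gte(ref$score + 1e-6, cross_correlation(s, mp))
  expect_lt(sqrt(sum(ref$translation^2)), 0.2)
  # displaced start converges back into the basin
  off <- nmrem:::new_placement(diag(3), c(3, 0, 0))
  back <- local_fit(s, mp, off)
  expect_lt(sqrt(sum(back$translation^2)), 0.5)
  expect_gte(back$score, cross_correlation(apply_placement(s, off), mp))
})

test_that("multi-copy docking returns separated, sorted placements", {
  fx <- fixture_a()
  lat <- fx$lattice
  pl <- dock_positions(fx$fold$structure, lat$map, n_positions = 4,
                       rotation_samples = 300)
  scores <- vapply(pl, `[[`, 0, "score")
  expect_true(all(diff(scores) <= 1e-12)) # descending
  com <- colMeans(coords(fx$fold$structure))
  centers <- t(vapply(pl, function(p) com + p$translation, numeric(3)))
  if (length(pl) > 1) {
    D <- as.matrix(dist(centers)); diag(D) <- Inf
    expect_gte(min(D), nmrem:::radius_of_gyration(coords(fx$fold$structure)))
  }
  # suppression caps a symmetric two-copy map at the requested single position
  two <- make_lattice(fx$fold$structure, n_copies = 2, spacing = 0,
                      axial_rise = 30, twist = 180, resolution = 8,
                      voxel = 2)
  one <- dock_positions(fx$fold$structure, two$map, n_positions = 1,
                        rotation_samples = 200)
  expect_length(one, 1)
})
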