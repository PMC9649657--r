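# Density maps and rigid-body docking. Maps are cubic-voxel 3-D grids with a
# real-space origin and a stated resolution; simulated density is a sum of
# per-atom isotropic Gaussians with sigma = resolution / (pi * sqrt(2)), a
# common EM convention. Docking scans a deterministic quasi-uniform rotation
# set over a translation grid, suppresses near-duplicate placements, and
# polishes survivors by gradient ascent on the real-space cross-correlation.

#' Construct a density map
#'
#' @param grid 3-D numeric array of density values
#' @param voxel voxel edge length (A)
#' @param origin real-space position of grid vertex (1,1,1) (A)
#' @param resolution stated resolution (A)
#' @return object of class `nmrem_map`
#' @export
new_density_map <- function(grid, voxel, origin = c(0, 0, 0),
                            resolution = NA_real_) {
  stopifnot(length(dim(grid)) == 3, voxel > 0, all(is.finite(grid)))
  structure(list(grid = grid, voxel = voxel, origin = as.numeric(origin),
                 resolution = resolution), class = "nmrem_map")
}

#' @export
print.nmrem_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<density map: %d x %d x %d voxels, %.2f A/voxel, resolution %s A>\n",
    d[1], d[2], d[3], x$voxel,
    if (is.na(x$resolution)) "?" else format(x$resolution)))
  invisible(x)
}

gaussian_sigma <- function(resolution) resolution / (pi * sqrt(2))

structure_coords_any <- function(x) {
  if (inherits(x, "nmrem_assembly"))
    do.call(rbind, lapply(x$subunits, coords))
  else if (inherits(x, "nmrem_structure")) coords(x)
  else if (is.matrix(x)) x
  else stop("expected a structure, assembly or coordinate matrix")
}

#' Simulate a density map from coordinates
#'
#' Sum of unit-weight per-atom isotropic Gaussians with
#' `sigma = resolution / (pi * sqrt(2))`, truncated at 3 sigma. Deterministic.
#'
#' @param x structure, assembly, list of structures, or coordinate matrix
#' @param resolution target resolution (A); must be at least twice the voxel
#' @param voxel voxel size (A)
#' @param selection atom selection (structures only)
#' @param padding empty border around the coordinates (A)
#' @param template optional `nmrem_map` whose grid geometry is reused (for
#'   correlation against an existing map)
#' @return an `nmrem_map`
#' @export
simulate_map <- function(x, resolution, voxel = resolution / 3,
                         selection = "heavy", padding = NULL,
                         template = NULL) {
  if (is.list(x) && !inherits(x, c("nmrem_structure", "nmrem_assembly"))) {
    X <- do.call(rbind, lapply(x, structure_coords_any))
  } else if (inherits(x, c("nmrem_structure", "nmrem_assembly")) &&
             !identical(selection, "heavy")) {
    if (inherits(x, "nmrem_assembly")) {
      X <- do.call(rbind, lapply(x$subunits, function(s)
        coords(s)[select_atoms(s, selection), , drop = FALSE]))
    } else {
      idx <- select_atoms(x, selection)
      if (length(idx) == 0) stop("empty selection")
      X <- coords(x)[idx, , drop = FALSE]
    }
  } else {
    X <- structure_coords_any(x)
  }
  if (nrow(X) == 0) stop("empty selection")
  sigma <- gaussian_sigma(resolution)
  if (!is.null(template)) {
    dims <- dim(template$grid); origin <- template$origin
    voxel <- template$voxel
  } else {
    if (resolution < 2 * voxel)
      stop("resolution must be at least twice the voxel size")
    if (is.null(padding)) padding <- 3 * sigma + 2 * voxel
    lo <- apply(X, 2, min) - padding
    hi <- apply(X, 2, max) + padding
    dims <- as.integer(ceiling((hi - lo) / voxel)) + 1L
    origin <- lo
  }
  # 4.5 sigma truncation keeps >99.8% of each 3-D Gaussian's mass (the
  # energy term truncates at 3 sigma for speed; correlations are robust to
  # the difference)
  g <- cpp_simulate_map(X, rep(1, nrow(X)), as.integer(dims),
                        as.numeric(origin), voxel, sigma, 4.5 * sigma)
  new_density_map(array(g, dim = dims), voxel, origin, resolution)
}

#' Real-space cross-correlation
#'
#' Pearson correlation of voxel values over a mask. For two maps on the same
#' grid the default mask is the set of voxels where either map exceeds
#' `threshold` times its maximum. For a structure against a map, the
#' structure's density is simulated on the map's grid at the map's stated
#' resolution and correlated over the map-derived mask.
#'
#' @param a `nmrem_map` or structure/assembly
#' @param b `nmrem_map`
#' @param mask optional logical array (same dims as the grids)
#' @param threshold mask threshold (fraction of each map's maximum)
#' @return correlation coefficient in `[-1, 1]`
#' @export
cross_correlation <- function(a, b, mask = NULL, threshold = 0.1) {
  if (!inherits(b, "nmrem_map")) stop("b must be a density map")
  if (!inherits(a, "nmrem_map")) {
    X <- structure_coords_any(a)
    ms <- map_spec(b, threshold)
    return(cpp_cc_grad(X, ms, FALSE)$cc)
  }
  if (!all(dim(a$grid) == dim(b$grid)))
    stop("maps must share one grid (resample first)")
  ga <- as.numeric(a$grid); gb <- as.numeric(b$grid)
  keep <- if (!is.null(mask)) as.logical(mask)
          else (ga > threshold * max(ga)) | (gb > threshold * max(gb))
  if (!any(keep)) stop("empty correlation mask")
  va <- ga[keep]; vb <- gb[keep]
  if (sd(va) == 0 || sd(vb) == 0) stop("constant map values under mask")
  stats::cor(va, vb)
}

# ---- MRC2014 I/O ----------------------------------------------------------

#' Read an MRC/CCP4 density map
#'
#' Supports MRC2014 modes 0 (int8), 1 (int16) and 2 (float32); axis order is
#' normalized so the returned grid is indexed (x, y, z) regardless of the
#' file's mapc/mapr/maps permutation. The origin is taken from the ORIGIN
#' header fields when set, otherwise from NXSTART/NYSTART/NZSTART.
#'
#' @param path MRC file
#' @param resolution stated resolution to attach (A), optional
#' @return an `nmrem_map`
#' @export
read_mrc <- function(path, resolution = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_dbl <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  if (nx <= 0 || ny <= 0 || nz <= 0 || !mode %in% c(0, 1, 2))
    stop("not a valid MRC file (bad dimensions or mode)")
  nstart <- hdr_int[5:7]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- hdr_dbl[11:13]
  mapc <- hdr_int[17]; mapr <- hdr_int[18]; maps <- hdr_int[19]
  if (!all(sort(c(mapc, mapr, maps)) == 1:3))
    stop("not a valid MRC file (bad axis correspondence)")
  origin_field <- hdr_dbl[50:52]
  nsymbt <- hdr_int[24]
  seek(con, 1024 + nsymbt)
  nvox <- nx * ny * nz
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                             signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"))
  if (length(data) < nvox) stop("truncated MRC data block")
  g <- array(data, dim = c(nx, ny, nz)) # file order: columns, rows, sections
  # permute so that axis 1 = x, 2 = y, 3 = z
  perm <- order(c(mapc, mapr, maps))
  if (!all(perm == 1:3)) g <- aperm(g, perm)
  voxel <- cella[1] / max(mx, 1)
  vox3 <- cella / pmax(c(mx, my, mz), 1)
  if (max(abs(vox3 - voxel)) > 1e-3)
    warning("anisotropic voxels; using the x spacing")
  ncrs_start <- nstart[perm]
  origin <- if (any(origin_field != 0)) origin_field
            else ncrs_start * voxel
  new_density_map(g, voxel, origin, resolution)
}

#' Write a density map as MRC2014 (mode 2, canonical axis order)
#' @param map an `nmrem_map`
#' @param path output path
#' @export
write_mrc <- function(map, path) {
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode: float32
  wi(c(0, 0, 0))             # nstart
  wi(d)                      # mx my mz
  wf(d * map$voxel)          # cell dimensions
  wf(c(90, 90, 90))          # cell angles
  wi(c(1, 2, 3))             # mapc mapr maps
  g <- as.numeric(map$grid)
  wf(c(min(g), max(g), mean(g)))
  wi(c(1, 0))                # ispg, nsymbt
  wi(rep(0, 25))             # extra (words 26-49, incl. exttyp/nversion zeroed)
  wf(map$origin)             # origin x y z (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian machine stamp
  wf(sd(g))
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  wf(g)
  invisible(path)
}

# ---- placements and docking -----------------------------------------------

new_placement <- function(rotation, translation, score = NA_real_) {
  stopifnot(abs(det(rotation) - 1) < 1e-6)
  list(rotation = rotation, translation = as.numeric(translation),
       score = score)
}

#' Apply a rigid placement to a structure
#'
#' Placements rotate about the structure's center of mass:
#' `x' = R (x - com) + com + t`.
#'
#' @param x a structure
#' @param placement list with `rotation`, `translation`
#' @return transformed structure
#' @export
apply_placement <- function(x, placement) {
  X <- coords(x)
  com <- colMeans(X)
  Xp <- sweep(sweep(X, 2, com) %*% t(placement$rotation), 2,
              com + placement$translation, `+`)
  coords(x) <- Xp
  x
}

placements_table <- function(placements) {
  do.call(rbind, lapply(seq_along(placements), function(k) {
    p <- placements[[k]]
    q <- matrix_to_quat(p$rotation)
    data.frame(rank = k, qw = q[1], qx = q[2], qy = q[3], qz = q[4],
               tx = p$translation[1], ty = p$translation[2],
               tz = p$translation[3], score = p$score)
  }))
}

#' Write placements as a TSV (quaternion, translation, score)
#' @param placements list of placements
#' @param path output path
#' @export
write_placements <- function(placements, path) {
  write.table(placements_table(placements), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

radius_of_gyration <- function(X) {
  sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))
}

#' Locally refine a rigid placement against a map
#'
#' Gradient ascent (BFGS over the 6 rigid parameters, analytic gradient
#' chained through the density model) on the real-space cross-correlation.
#' The returned score is never below the input score.
#'
#' @param x structure to place
#' @param map target `nmrem_map`
#' @param placement starting placement
#' @param maxit iteration cap
#' @param threshold mask threshold for the correlation
#' @return refined placement
#' @export
local_fit <- function(x, map, placement, maxit = 60, threshold = 0.1) {
  X0 <- coords(x)
  com <- colMeans(X0)
  Xc <- sweep(X0, 2, com)
  ms <- map_spec(map, threshold)
  R0 <- placement$rotation
  par0 <- c(0, 0, 0, placement$translation)
  score_at <- function(par) {
    R <- rotvec_to_matrix(par[1:3]) %*% R0
    Xp <- sweep(Xc %*% t(R), 2, com + par[4:6], `+`)
    cpp_cc_grad(Xp, ms, FALSE)$cc
  }
  fn <- function(par) -score_at(par)
  gr <- function(par) {
    R <- rotvec_to_matrix(par[1:3]) %*% R0
    Xp <- sweep(Xc %*% t(R), 2, com + par[4:6], `+`)
    res <- cpp_cc_grad(Xp, ms, TRUE)
    G <- res$grad                       # dCC/dx', n x 3
    gt <- colSums(G)                    # translation gradient
    # rotation-vector gradient at 0: dx'/dtheta_k = e_k x (x' - center)
    Y <- sweep(Xp, 2, com + par[4:6])
    gw <- c(sum(Y[, 2] * G[, 3] - Y[, 3] * G[, 2]),
            sum(Y[, 3] * G[, 1] - Y[, 1] * G[, 3]),
            sum(Y[, 1] * G[, 2] - Y[, 2] * G[, 1]))
    -c(gw, gt)
  }
  cc0 <- tryCatch(score_at(par0), error = function(e)
    stop("placement does not overlap the map"))
  opt <- tryCatch(
    optim(par0, fn, gr, method = "BFGS", control = list(maxit = maxit)),
    error = function(e) list(par = par0, value = -cc0))
  if (-opt$value >= cc0) {
    par <- opt$par; cc <- -opt$value
  } else {
    par <- par0; cc <- cc0
  }
  new_placement(rotvec_to_matrix(par[1:3]) %*% R0, par[4:6], cc)
}

#' Multi-position rigid-body docking into a density map
#'
#' Scans a deterministic quasi-uniform rotation set against a translation
#' grid, scoring candidate poses by the mean interpolated map density at the
#' probe atoms; the best candidates are locally refined by [local_fit()]
#' (real-space cross-correlation), sorted by descending CC, and thinned so
#' that retained placements are at least `min_separation` apart
#' (non-maximum suppression on the center of mass).
#'
#' @param x structure to dock
#' @param map target `nmrem_map`
#' @param n_positions number of placements requested
#' @param rotation_samples size of the rotation search set
#' @param min_separation minimum center-of-mass separation between returned
#'   placements (default: the radius of gyration of the chain)
#' @param translation_step translation grid spacing (default: 2 voxels)
#' @param probe_selection atoms used for coarse scoring
#' @param refine_top number of candidates polished per requested position
#' @return list of placements sorted by descending score (class
#'   `nmrem_placements`); fewer than requested triggers a warning
#' @export
dock_positions <- function(x, map, n_positions = 1, rotation_samples = 500,
                           min_separation = NULL, translation_step = NULL,
                           probe_selection = "name CA", refine_top = 4) {
  X <- coords(x)
  com <- colMeans(X)
  if (is.null(min_separation)) min_separation <- radius_of_gyration(X)
  if (is.null(translation_step)) translation_step <- 2 * map$voxel
  probe_idx <- select_atoms(x, probe_selection)
  probe <- sweep(X[probe_idx, , drop = FALSE], 2, com)
  quats <- rotation_samples(rotation_samples)
  d <- dim(map$grid)
  lo <- map$origin
  hi <- map$origin + (d - 1) * map$voxel
  tr_dims <- pmax(1L, as.integer(floor((hi - lo) / translation_step)) + 1L)
  res <- cpp_coarse_dock(as.numeric(map$grid), as.integer(d),
                         as.numeric(lo), map$voxel, probe, quats,
                         as.numeric(lo), tr_dims, translation_step)
  score <- array(res$score, dim = tr_dims)
  rot <- array(res$rot, dim = tr_dims)
  # candidate translations: local maxima of the coarse score, best first
  ord <- order(score, decreasing = TRUE)
  n_cand <- min(length(ord), max(50, refine_top * n_positions * 3))
  cand <- ord[seq_len(n_cand)]
  grid_xyz <- function(lin) {
    lin0 <- lin - 1
    i <- lin0 %% tr_dims[1]
    j <- (lin0 %/% tr_dims[1]) %% tr_dims[2]
    k <- lin0 %/% (tr_dims[1] * tr_dims[2])
    cbind(lo[1] + i * translation_step, lo[2] + j * translation_step,
          lo[3] + k * translation_step)
  }
  pos <- grid_xyz(cand)
  # coarse non-max suppression at half the separation to keep diversity
  keep <- rep(TRUE, nrow(pos))
  for (a in seq_len(nrow(pos))) {
    if (!keep[a]) next
    if (a < nrow(pos)) {
      later <- (a + 1):nrow(pos)
      d2 <- rowSums(sweep(pos[later, , drop = FALSE], 2, pos[a, ])^2)
      keep[later[d2 < (min_separation / 2)^2]] <- FALSE
    }
  }
  cand <- cand[keep][seq_len(min(sum(keep), refine_top * n_positions))]
  pos <- grid_xyz(cand)
  refined <- vector("list", length(cand))
  for (k in seq_along(cand)) {
    R <- quat_to_matrix(quats[rot[cand[k]] + 1, ])
    # coarse placement: rotate about com, translate com onto grid point
    pl <- new_placement(R, pos[k, ] - com, score[cand[k]])
    refined[[k]] <- tryCatch(local_fit(x, map, pl),
                             error = function(e) NULL)
  }
  refined <- Filter(Negate(is.null), refined)
  refined <- refined[order(vapply(refined, `[[`, 0, "score"),
                           decreasing = TRUE)]
  # final non-max suppression at full separation on placed centers
  centers <- t(vapply(refined, function(p) com + p$translation, numeric(3)))
  out <- list()
  for (k in seq_along(refined)) {
    if (length(out) == n_positions) break
    ok <- TRUE
    for (p in out) {
      if (sum((com + p$translation - centers[k, ])^2) < min_separation^2) {
        ok <- FALSE; break
      }
    }
    if (ok) out[[length(out) + 1]] <- refined[[k]]
  }
  if (length(out) < n_positions)
    warning("only ", length(out), " of ", n_positions,
            " placements satisfy the separation constraint")
  structure(out, class = "nmrem_placements")
}

#' @export
print.nmrem_placements <- function(x, ...) {
  cat(sprintf("<%d placement(s), scores %s>\n", length(x),
              paste(sprintf("%.3f", vapply(x, `[[`, 0, "score")),
                    collapse = ", ")))
  invisible(x)
}
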