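# Synthetic ground-truth generators: toy folds with ideal geometry,
# sparse-labeling-filtered carbon-carbon peak lists with controlled ambiguity,
# noisy torsion restraints, multi-copy helical lattices with blurred density
# maps, and perturbed second-state peak lists. Every generator is a
# deterministic function of (parameters, seed), and every emitted restraint is
# satisfied by the true coordinates.

#' Sparse-labeling visibility schemes
#'
#' Simplified residue-type masks naming the NMR-visible carbon atoms of each
#' labeling scheme: `uniform_13C` sees every carbon; `glucose_16`
#' (1,6-13C-glucose) is modeled as dominated by the carbonyl and the terminal
#' sidechain carbon (C', CD), the positions fed by glucose C1/C6;
#' `glucose_2` (2-13C-glucose) as Calpha-dominated (CA, CG). These masks are
#' deliberately coarse stand-ins for the true isotopomer statistics.
#'
#' @param name scheme name
#' @param visible optional custom character vector of visible atom names
#' @return list with `name` and `visible`
#' @export
labeling_scheme <- function(name = c("uniform_13C", "glucose_16", "glucose_2"),
                            visible = NULL) {
  name <- match.arg(name)
  if (is.null(visible))
    visible <- switch(name,
                      uniform_13C = c("CA", "C", "CB", "CG", "CD"),
                      glucose_16 = c("C", "CD"),
                      glucose_2 = c("CA", "CG"))
  list(name = name, visible = visible)
}

element_torsions <- function(element) {
  switch(element,
         helix = c(-60, -45),
         strand = c(-120, 120),
         loop = c(-75, 150),
         stop("unknown topology element: ", element))
}

# 4-residue reversing-turn motif used for "loop" elements so the flanking
# elements pack against each other (chosen once by construction: it yields an
# antiparallel hairpin with inter-element contacts but no clashes)
TURN_MOTIF <- list(c(-120, 120), c(-120, 120), c(60, 45), c(-140, 160))

#' Generate a toy fold with known ground truth
#'
#' Builds an ideal-geometry chain whose backbone torsions follow the given
#' secondary-structure plan (`"helix"`, `"strand"`, `"loop"` tokens separated
#' by dashes, residues split evenly), with pseudo-sidechain carbons. The
#' sequence is drawn deterministically from the seed.
#'
#' @param n_residues chain length (>= 5)
#' @param topology_spec e.g. `"helix-loop-strand"`
#' @param seed RNG seed
#' @return list with `structure` and `truth` (seed, element map, torsions)
#' @export
make_toy_fold <- function(n_residues, topology_spec = "helix-loop-helix",
                          seed = 1) {
  stopifnot(n_residues >= 5)
  elements <- strsplit(topology_spec, "-")[[1]]
  for (e in elements) element_torsions(e) # validate tokens
  nel <- length(elements)
  # loops are fixed 4-residue reversing turns; the rest is split evenly
  nloop <- sum(elements == "loop")
  loop_size <- if (nloop > 0) min(4L, max(1L, (n_residues - nel) %/%
                                            max(1, nel))) else 0L
  rest <- n_residues - nloop * loop_size
  nrest <- nel - nloop
  sizes <- integer(nel)
  if (nrest > 0) {
    base <- rest %/% nrest
    sizes[elements != "loop"] <- base
    sizes[which(elements != "loop")[1]] <- base + rest %% nrest
  }
  sizes[elements == "loop"] <- loop_size
  elem_of <- rep(elements, sizes)
  phi <- psi <- numeric(n_residues)
  loop_pos <- 0L
  for (i in seq_len(n_residues)) {
    if (elem_of[i] == "loop") {
      loop_pos <- loop_pos + 1L
      t <- TURN_MOTIF[[(loop_pos - 1L) %% length(TURN_MOTIF) + 1L]]
    } else {
      loop_pos <- 0L
      t <- element_torsions(elem_of[i])
    }
    phi[i] <- t[1]; psi[i] <- t[2]
  }
  set.seed(seed)
  # varied composition, biased toward residues with 1-3 sidechain carbons
  pool <- c("A", "L", "K", "E", "V", "T", "I", "S", "F", "D", "N", "Q", "G")
  sequence <- paste(sample(pool, n_residues, replace = TRUE), collapse = "")
  atoms <- build_chain_atoms(sequence, phi, psi)
  s <- new_structure(atoms, sequence = sequence)
  s <- relieve_sidechain_clashes(s)
  list(structure = s,
       truth = list(seed = seed, elements = elem_of, phi = phi, psi = psi))
}

# Deterministic sidechain clash relief: for each residue whose pseudo
# sidechain comes within 2.2 A of atoms two or more residues away, try the
# three staggered chi1 (and chi2) rotamers and keep the combination with the
# largest clearance. Rotating chi preserves ideal covalent geometry exactly
# (chi is not a topology term), so built folds keep zero geometry deviations.
relieve_sidechain_clashes <- function(s, clearance = 2.2, passes = 3) {
  rot <- c(-60, 180, 60)
  g <- GEOM
  for (pass in seq_len(passes)) {
    X <- coords(s)
    at <- s$atoms
    moved <- FALSE
    for (r in sort(unique(at$resi))) {
      side <- which(at$resi == r & at$atom %in% SIDE_NAMES[-1]) # CG, CD
      if (length(side) == 0) next
      others <- which(abs(at$resi - r) >= 2)
      score <- function(Xs) {
        min(vapply(seq_len(nrow(Xs)), function(m)
          sqrt(min(rowSums(sweep(X[others, , drop = FALSE], 2,
                                 Xs[m, ])^2))), 0))
      }
      iN <- which(at$resi == r & at$atom == "N")
      iCA <- which(at$resi == r & at$atom == "CA")
      iCB <- which(at$resi == r & at$atom == "CB")
      iCG <- which(at$resi == r & at$atom == "CG")
      iCD <- which(at$resi == r & at$atom == "CD")
      cur <- score(X[side, , drop = FALSE])
      if (cur >= clearance) next
      best <- list(score = cur, X = X[side, , drop = FALSE])
      for (c1 in rot) for (c2 in if (length(iCD)) rot else 180) {
        CG <- nerf_place(X[iN, ], X[iCA, ], X[iCB, ], g$b_CB_CG,
                         g$a_CA_CB_CG, c1)
        Xs <- matrix(CG, 1, 3)
        if (length(iCD)) {
          CD <- nerf_place(X[iCA, ], X[iCB, ], CG, g$b_CG_CD,
                           g$a_CB_CG_CD, c2)
          Xs <- rbind(Xs, CD)
        }
        sc <- score(Xs)
        if (sc > best$score + 1e-9) best <- list(score = sc, X = Xs)
      }
      if (best$score > cur + 1e-9) {
        X[side, ] <- best$X
        moved <- TRUE
      }
    }
    coords(s) <- X
    if (!moved) break
  }
  s
}

# deterministic pseudo chemical shift (ppm) for a (residue index, atom) site
BASE_SHIFT <- c(CA = 55, CB = 32, CG = 30, CD = 28, C = 175)

pseudo_shifts <- function(structure, seed) {
  at <- structure$atoms
  carb <- which(at$elem == "C")
  set.seed(seed + 1000L)
  # per-site dispersion around the atom-type base shift
  data.frame(resi = at$resi[carb], atom = at$atom[carb],
             shift = BASE_SHIFT[at$atom[carb]] +
               round(rnorm(length(carb), 0, 2.5), 3),
             stringsAsFactors = FALSE)
}

#' Simulate a cross-peak list from a structure
#'
#' Emits one peak per pair of NMR-visible carbons within the distance cutoff
#' (the sparse-labeling detection limit). A seeded fraction of the peaks
#' receives 1 to `max_ambiguity - 1` decoy candidate assignments drawn from
#' other visible carbon pairs (decoys at least 2.5 A apart so the true
#' coordinates still satisfy the resulting r^-6 restraint bounds). Every
#' emitted true contact is within the cutoff, so the ground truth incurs zero
#' restraint energy.
#'
#' @param structure the true structure
#' @param scheme a [labeling_scheme()]
#' @param cutoff detection cutoff (A); 7.2 A and below keeps restraints
#'   consistent with the inter-residue upper bound
#' @param ambiguity_rate fraction of peaks made ambiguous
#' @param max_ambiguity candidate-assignment cap (restraint prep drops beyond)
#' @param noise chemical-shift noise sd (ppm)
#' @param seed RNG seed
#' @return list with `peaks` (data.frame) and `truth` (planted contacts,
#'   shift table, seed)
#' @export
simulate_peaks <- function(structure, scheme = labeling_scheme("uniform_13C"),
                           cutoff = 7.2, ambiguity_rate = 0,
                           max_ambiguity = 5, noise = 0, seed = 1) {
  at <- structure$atoms
  vis <- which(at$elem == "C" & at$atom %in% scheme$visible)
  if (length(vis) == 0) stop("labeling scheme has no visible atoms")
  X <- coords(structure)
  peaks <- NULL
  if (cutoff > 0 && length(vis) >= 2) {
    pr <- t(combn(vis, 2))
    d <- sqrt(rowSums((X[pr[, 1], , drop = FALSE] -
                       X[pr[, 2], , drop = FALSE])^2))
    # detection window: within the cutoff and above the restraint lower
    # bound of the pair's class (sub-contact distances are construction
    # artifacts of the toy and would make the bounds unsatisfiable)
    lower_ok <- ifelse(at$resi[pr[, 1]] == at$resi[pr[, 2]],
                       d >= 1.5, d >= 2.0)
    keep <- d <= cutoff & lower_ok
    pr <- pr[keep, , drop = FALSE]; d <- d[keep]
  } else {
    pr <- matrix(0L, 0, 2); d <- numeric(0)
  }
  shifts <- pseudo_shifts(structure, seed)
  skey <- paste(shifts$resi, shifts$atom)
  shift_of <- function(idx)
    shifts$shift[match(paste(at$resi[idx], at$atom[idx]), skey)]
  set.seed(seed)
  n <- nrow(pr)
  if (n > 0) {
    # decoy assignments are added only to inter-residue peaks, and only from
    # inter-residue pairs at least 3.5 A apart, so the r^-6-summed effective
    # distance of the resulting ambiguous restraint stays within the
    # inter-residue bounds at the true coordinates (master guarantee)
    inter_peak <- at$resi[pr[, 1]] != at$resi[pr[, 2]]
    amb_flag <- runif(n) < ambiguity_rate & inter_peak
    alt <- character(n)
    for (p in which(amb_flag)) {
      ndecoy <- sample(seq_len(max_ambiguity - 1), 1)
      toks <- character(0)
      dinv6 <- d[p]^-6
      tries <- 0
      while (length(toks) < ndecoy && tries < 50) {
        tries <- tries + 1
        ij <- sample(vis, 2)
        if (at$resi[ij[1]] == at$resi[ij[2]]) next
        dd <- sqrt(sum((X[ij[1], ] - X[ij[2], ])^2))
        if (dd < 3.5) next
        if ((dinv6 + sum(dd^-6))^(-1 / 6) < 2.0) next
        dinv6 <- dinv6 + dd^-6
        toks <- union(toks, sprintf("%d.%s-%d.%s",
                                    at$resi[ij[1]], at$atom[ij[1]],
                                    at$resi[ij[2]], at$atom[ij[2]]))
      }
      alt[p] <- paste(toks, collapse = ";")
    }
    peaks <- data.frame(
      exp_id = paste0(scheme$name, "_cord"),
      res_i = at$resi[pr[, 1]], atom_i = at$atom[pr[, 1]],
      res_j = at$resi[pr[, 2]], atom_j = at$atom[pr[, 2]],
      shift1_ppm = shift_of(pr[, 1]) + rnorm(n, 0, noise),
      shift2_ppm = shift_of(pr[, 2]) + rnorm(n, 0, noise),
      intensity = round(100 * (3 / pmax(d, 3))^3, 3),
      alt_assignments = alt, stringsAsFactors = FALSE)
  } else {
    peaks <- data.frame(exp_id = character(0), res_i = integer(0),
                        atom_i = character(0), res_j = integer(0),
                        atom_j = character(0), shift1_ppm = numeric(0),
                        shift2_ppm = numeric(0), intensity = numeric(0),
                        alt_assignments = character(0))
  }
  list(peaks = peaks,
       truth = list(contacts = data.frame(
         res_i = at$resi[pr[, 1]], atom_i = at$atom[pr[, 1]],
         res_j = at$resi[pr[, 2]], atom_j = at$atom[pr[, 2]],
         distance = d), shifts = shifts, seed = seed))
}

#' Simulate torsion restraints from a structure
#'
#' Measures phi/psi from the true coordinates and adds Gaussian noise to the
#' targets; the true structure violates no restraint whose noise draw stays
#' within the tolerance. Chain ends contribute (n-1) phi and (n-1) psi.
#'
#' @param structure the true structure
#' @param tolerance restraint tolerance (degrees)
#' @param noise target noise sd (degrees)
#' @param seed RNG seed
#' @return torsion data.frame (`resi`, `angle`, `target`, `tolerance`)
#' @export
simulate_torsions <- function(structure, tolerance = 20, noise = 0,
                              seed = 1) {
  stopifnot(n_residues(structure) >= 3)
  tor <- measure_torsions(structure)
  set.seed(seed)
  rows <- list()
  for (k in seq_len(nrow(tor))) {
    if (!is.na(tor$phi[k]))
      rows[[length(rows) + 1]] <- data.frame(
        resi = tor$resi[k], angle = "phi",
        target = wrap_angle(tor$phi[k] + rnorm(1, 0, noise)),
        tolerance = tolerance)
    if (!is.na(tor$psi[k]))
      rows[[length(rows) + 1]] <- data.frame(
        resi = tor$resi[k], angle = "psi",
        target = wrap_angle(tor$psi[k] + rnorm(1, 0, noise)),
        tolerance = tolerance)
  }
  do.call(rbind, rows)
}

#' Build a helical multi-copy lattice and its density map
#'
#' Places `n_copies` of the chain on a helical lattice (radial offset
#' `spacing` from the axis, `axial_rise` per copy along z, `twist` degrees per
#' copy about z), checks for inter-copy clashes, simulates the blurred map of
#' the whole lattice, and records the true placements.
#'
#' @param structure single-copy template
#' @param n_copies number of copies
#' @param spacing radial offset from the helix axis (A)
#' @param axial_rise rise per copy (A)
#' @param twist rotation per copy (degrees)
#' @param resolution map resolution (A)
#' @param voxel map voxel size (A)
#' @param seed recorded in the ground truth (placement is deterministic)
#' @return list with `assembly`, `map`, `truth` (placements as
#'   rotation/translation about the template center of mass)
#' @export
make_lattice <- function(structure, n_copies = 4, spacing = 30,
                         axial_rise = 22, twist = 30, resolution = 8,
                         voxel = 2, seed = 1) {
  X0 <- coords(structure)
  com <- colMeans(X0)
  # recenter the template at (spacing, 0, 0)
  base <- sweep(X0, 2, com) # centered
  asm <- replicate_subunits(structure, n_copies)
  placements <- vector("list", n_copies)
  for (k in seq_len(n_copies)) {
    ang <- deg2rad(twist * (k - 1))
    Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    center_k <- as.numeric(Rz %*% c(spacing, 0, 0)) +
      c(0, 0, axial_rise * (k - 1))
    Xk <- sweep(base %*% t(Rz), 2, center_k, `+`)
    coords(asm$subunits[[k]]) <- Xk
    placements[[k]] <- new_placement(Rz, center_k - com)
  }
  # clash check between copies
  for (a in seq_len(n_copies - 1)) for (b in (a + 1):n_copies) {
    Xa <- coords(asm$subunits[[a]]); Xb <- coords(asm$subunits[[b]])
    dmin <- min(vapply(seq_len(nrow(Xa)), function(i)
      min(rowSums(sweep(Xb, 2, Xa[i, ])^2)), 0))
    if (sqrt(dmin) < 2.0)
      stop("copies ", a, " and ", b, " clash; increase spacing or rise")
  }
  map <- simulate_map(asm, resolution = resolution, voxel = voxel)
  list(assembly = asm, map = map,
       truth = list(placements = placements, seed = seed,
                    spacing = spacing, axial_rise = axial_rise,
                    twist = twist))
}

#' Perturb a peak list into a second sample state
#'
#' Peaks whose primary assignment touches a perturbed residue have their two
#' shift dimensions displaced by `shift_delta` ppm (in a seeded direction, so
#' the resulting CSP equals `shift_delta` exactly) and their intensities
#' scaled by `intensity_factor`; all other peaks are untouched.
#'
#' @param structure the structure (for bookkeeping only)
#' @param peaks peak data.frame of the reference state
#' @param perturbed_residues residue indices of the perturbation site
#' @param shift_delta CSP magnitude (ppm)
#' @param intensity_factor intensity scale of the perturbed state
#' @param seed RNG seed (perturbation directions)
#' @return list with `peaks` (second state) and `truth` (perturbed set)
#' @export
perturb_state <- function(structure, peaks, perturbed_residues,
                          shift_delta = 0.5, intensity_factor = 0.5,
                          seed = 1) {
  nres <- n_residues(structure)
  if (length(perturbed_residues) > 0 &&
      (min(perturbed_residues) < 1 || max(perturbed_residues) > nres))
    stop("perturbed residues outside the chain")
  out <- peaks
  touched <- peaks$res_i %in% perturbed_residues |
    peaks$res_j %in% perturbed_residues
  set.seed(seed)
  if (any(touched)) {
    theta <- runif(sum(touched), 0, 2 * pi)
    out$shift1_ppm[touched] <- out$shift1_ppm[touched] +
      shift_delta * cos(theta)
    out$shift2_ppm[touched] <- out$shift2_ppm[touched] +
      shift_delta * sin(theta)
    out$intensity[touched] <- out$intensity[touched] * intensity_factor
  }
  list(peaks = out,
       truth = list(perturbed_residues = sort(unique(perturbed_residues)),
                    shift_delta = shift_delta,
                    intensity_factor = intensity_factor, seed = seed))
}

#' The standard synthetic fixture ("fixture A")
#'
#' 30-residue helix-loop-helix fold, glucose_16 labeling, 7.2 A detection
#' cutoff, 15% ambiguous peaks, 4-copy helical lattice with an 8 A map;
#' master seed 7. Optionally writes the text inputs (peaks, torsions, truth
#' PDB, truth JSON) and the map (MRC) to a directory; the files are
#' regenerated bit-exactly by this call.
#'
#' @param dir optional output directory
#' @param seed master seed (default 7)
#' @param include_binary also write the MRC map and the multi-copy lattice
#'   PDB (the text inputs alone are what the package ships; the map is
#'   regenerated bit-exactly from the seed)
#' @return list with `fold`, `peaks`, `torsions`, `restraints`, `lattice`
#' @export
fixture_a <- function(dir = NULL, seed = 7, include_binary = TRUE) {
  fold <- make_toy_fold(30, "helix-loop-helix", seed = seed)
  pk <- simulate_peaks(fold$structure, labeling_scheme("glucose_16"),
                       cutoff = 7.2, ambiguity_rate = 0.15,
                       max_ambiguity = 5, seed = seed)
  tor <- simulate_torsions(fold$structure, tolerance = 20, noise = 0,
                           seed = seed)
  lat <- make_lattice(fold$structure, n_copies = 4, spacing = 30,
                      axial_rise = 22, twist = 30, resolution = 8,
                      voxel = 2, seed = seed)
  restraints <- peaks_to_restraints(pk$peaks)
  # 17 additional restraints for the mobile tail (residues 23-30), the toy
  # analogue of the extra neck-linker restraint set
  pk_link <- simulate_peaks(fold$structure, labeling_scheme("uniform_13C"),
                            cutoff = 7.2, seed = seed + 500L)$peaks
  touch <- (pk_link$res_i >= 23 | pk_link$res_j >= 23) &
    abs(pk_link$res_i - pk_link$res_j) >= 2
  pk_link <- pk_link[touch, ]
  set.seed(seed)
  pk_link <- pk_link[sample(nrow(pk_link), min(17, nrow(pk_link))), ]
  linker_restraints <- peaks_to_restraints(pk_link)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_peaks(pk$peaks, file.path(dir, "peaks.tsv"))
    write_torsions(tor, file.path(dir, "torsions.tsv"))
    write_structure(fold$structure, file.path(dir, "truth.pdb"))
    if (include_binary) {
      write_structure(lat$assembly, file.path(dir, "lattice.pdb"))
      write_mrc(lat$map, file.path(dir, "map.mrc"))
    }
    truth <- list(seed = seed,
                  placements = lapply(lat$truth$placements, function(p)
                    list(quaternion = matrix_to_quat(p$rotation),
                         translation = p$translation)),
                  n_restraints = length(restraints))
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = 8),
               file.path(dir, "truth.json"))
  }
  list(fold = fold, peaks = pk, torsions = tor, restraints = restraints,
       linker_restraints = linker_restraints, lattice = lat, seed = seed)
}
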