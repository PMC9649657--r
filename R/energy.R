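# Differentiable energy terms. All terms are evaluated in compiled code with
# analytic gradients; this file assembles the term specification from
# structures, restraints and maps. Units: kcal/mol, Angstrom; dihedral force
# constants are per rad^2 (inputs in degrees are converted at this boundary).

#' Energy-term configuration
#'
#' Force constants and switches for the energy terms. Setting a force
#' constant to 0 disables the corresponding term exactly.
#'
#' @param k_bond,k_angle,k_improper covalent-geometry force constants
#'   (kcal/mol/A^2 for bonds; kcal/mol/rad^2 for angles and impropers)
#' @param k_dist distance-restraint force constant (kcal/mol/A^2); annealing
#'   schedules ramp this from 2 to 30
#' @param k_dih dihedral-restraint force constant (kcal/mol/rad^2); 10 during
#'   high-temperature dynamics, 200 during cooling
#' @param k_map density cross-correlation force constant (kcal/mol)
#' @param k_ncs,tol_ncs non-crystallographic-symmetry force constant
#'   (kcal/mol/A^2 on the RMSD excess) and tolerance (A)
#' @param k_repel,r_repel soft-sphere repulsion constant and onset distance
#' @param k_rgyr,rgyr_target weak radius-of-gyration restraint
#'   (gyration-volume surrogate); forced off when a map term is present
#' @param dih_tol_default dihedral tolerance used when a torsion table has
#'   none (degrees)
#' @param map_selection atom selection entering the map term
#' @param map_residue_mask residue indices entering the map term (NULL = all)
#' @param map_threshold mask threshold as a fraction of the map maximum
#' @return a list of class `nmrem_energy_config`
#' @export
energy_config <- function(k_bond = 600, k_angle = 120, k_improper = 100,
                          k_dist = 30, k_dih = 200, k_map = 50,
                          k_ncs = 100, tol_ncs = 1.0,
                          k_repel = 4, r_repel = 2.0,
                          k_rgyr = 0, rgyr_target = NA,
                          dih_tol_default = 20,
                          map_selection = "backbone",
                          map_residue_mask = NULL,
                          map_threshold = 0.1) {
  structure(list(k_bond = k_bond, k_angle = k_angle, k_improper = k_improper,
                 k_dist = k_dist, k_dih = k_dih, k_map = k_map,
                 k_ncs = k_ncs, tol_ncs = tol_ncs, k_repel = k_repel,
                 r_repel = r_repel, k_rgyr = k_rgyr,
                 rgyr_target = rgyr_target,
                 dih_tol_default = dih_tol_default,
                 map_selection = map_selection,
                 map_residue_mask = map_residue_mask,
                 map_threshold = map_threshold),
            class = "nmrem_energy_config")
}

#' Read an energy/pipeline configuration from a JSON file
#' @param path JSON file; fields override [energy_config()] defaults
#' @return `nmrem_energy_config`
#' @export
read_energy_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  cfg <- energy_config()
  for (nm in names(vals)) cfg[[nm]] <- vals[[nm]]
  cfg
}

# resolve restraint assignments to 1-based atom indices of `atoms`
resolve_restraints <- function(restraints, atoms) {
  pairs <- list(); offs <- integer(length(restraints) + 1); offs[1] <- 0L
  lower <- upper <- numeric(length(restraints))
  for (k in seq_along(restraints)) {
    r <- restraints[[k]]
    a <- r$assignments
    pi <- atom_lookup(atoms, a$res_i, a$atom_i)
    pj <- atom_lookup(atoms, a$res_j, a$atom_j)
    bad <- which(pi == 0 | pj == 0)
    if (length(bad) > 0)
      stop("restraint ", k, ": cannot resolve atom ",
           a$res_i[bad[1]], ".", a$atom_i[bad[1]], " - ",
           a$res_j[bad[1]], ".", a$atom_j[bad[1]])
    pairs[[k]] <- cbind(pi, pj)
    offs[k + 1] <- offs[k] + nrow(a)
    lower[k] <- r$lower; upper[k] <- r$upper
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs)
       else matrix(0L, 0, 2),
       offsets = offs, lower = lower, upper = upper)
}

# resolve torsion table to 4-atom quadruples (1-based)
resolve_torsions <- function(torsions, atoms, tol_default = 20) {
  if (is.null(torsions) || nrow(torsions) == 0)
    return(list(quads = matrix(0L, 0, 4), target = numeric(0),
                tol = numeric(0)))
  torsions <- validate_torsions(torsions)
  quads <- matrix(0L, nrow(torsions), 4)
  for (m in seq_len(nrow(torsions))) {
    r <- torsions$resi[m]
    q <- if (torsions$angle[m] == "phi")
      c(atom_lookup(atoms, r - 1, "C"), atom_lookup(atoms, r, "N"),
        atom_lookup(atoms, r, "CA"), atom_lookup(atoms, r, "C"))
    else
      c(atom_lookup(atoms, r, "N"), atom_lookup(atoms, r, "CA"),
        atom_lookup(atoms, r, "C"), atom_lookup(atoms, r + 1, "N"))
    if (any(q == 0))
      stop("torsion restraint ", torsions$angle[m], " ", r,
           ": atoms not present")
    quads[m, ] <- q
  }
  list(quads = quads, target = torsions$target,
       tol = ifelse(is.na(torsions$tolerance), tol_default,
                    torsions$tolerance))
}

map_spec <- function(map, threshold = 0.1) {
  g <- as.numeric(map$grid)
  mx <- max(g)
  mask <- which(g > threshold * mx) - 1L
  if (length(mask) == 0) stop("empty map mask")
  sigma <- map$resolution / (pi * sqrt(2))
  list(grid = g, dims = dim(map$grid), origin = map$origin,
       voxel = map$voxel, sigma = sigma, cutoff = 3 * sigma,
       mask = as.integer(mask))
}

#' Assemble an energy system
#'
#' Combines a structure (or assembly), resolved distance and torsion
#' restraints, covalent topology and an optional density map into the
#' term specification evaluated by [total_energy()], [minimize()] and the
#' annealing engine. For an assembly, restraints are applied to every subunit
#' and an NCS similarity term couples the subunits.
#'
#' @param x `nmrem_structure` or `nmrem_assembly`
#' @param restraints optional `nmrem_restraints`
#' @param torsions optional torsion data.frame
#' @param map optional `nmrem_map` density map
#' @param config an [energy_config()]
#' @return object of class `nmrem_system`
#' @export
make_system <- function(x, restraints = NULL, torsions = NULL, map = NULL,
                        config = energy_config()) {
  is_assembly <- inherits(x, "nmrem_assembly")
  if (is_assembly) {
    nsub <- length(x$subunits)
    per <- nrow(x$subunits[[1]]$atoms)
    atoms <- do.call(rbind, lapply(x$subunits, `[[`, "atoms"))
    rownames(atoms) <- NULL
    top1 <- x$subunits[[1]]$topology
    if (is.null(top1)) stop("assembly template has no topology")
    offset_df <- function(df, cols, off) {
      for (cc in cols) df[[cc]] <- df[[cc]] + off
      df
    }
    tops <- lapply(seq_len(nsub) - 1L, function(m) {
      list(bonds = offset_df(top1$bonds, c("i", "j"), m * per),
           angles = offset_df(top1$angles, c("i", "j", "k"), m * per),
           impropers = offset_df(top1$impropers, c("i", "j", "k", "l"),
                                 m * per))
    })
    topology <- list(bonds = do.call(rbind, lapply(tops, `[[`, "bonds")),
                     angles = do.call(rbind, lapply(tops, `[[`, "angles")),
                     impropers = do.call(rbind,
                                         lapply(tops, `[[`, "impropers")))
    sub_idx <- lapply(seq_len(nsub) - 1L, function(m) m * per + seq_len(per))
  } else {
    nsub <- 1L
    atoms <- x$atoms
    topology <- x$topology %||% empty_topology()
    per <- nrow(atoms)
    sub_idx <- list(seq_len(per))
  }
  n <- nrow(atoms)
  spec <- list()
  if (config$k_bond > 0 && nrow(topology$bonds) > 0) {
    spec$bonds <- as.matrix(topology$bonds[, c("i", "j")]) - 1L
    spec$bond_r0 <- topology$bonds$r0
    spec$k_bond <- config$k_bond
  }
  if (config$k_angle > 0 && nrow(topology$angles) > 0) {
    spec$angles <- as.matrix(topology$angles[, c("i", "j", "k")]) - 1L
    spec$angle_t0 <- deg2rad(topology$angles$th0)
    spec$k_angle <- config$k_angle
  }
  if (config$k_improper > 0 && nrow(topology$impropers) > 0) {
    spec$impropers <- as.matrix(topology$impropers[, c("i", "j", "k", "l")]) - 1L
    spec$impr_t0 <- deg2rad(topology$impropers$phi0)
    spec$k_impr <- config$k_improper
  }
  if (!is.null(torsions) && nrow(torsions) > 0 && config$k_dih > 0) {
    base <- if (is_assembly) x$subunits[[1]]$atoms else atoms
    rt <- resolve_torsions(torsions, base, config$dih_tol_default)
    quads <- do.call(rbind, lapply(seq_len(nsub) - 1L,
                                   function(m) rt$quads + m * per))
    spec$dihres <- quads - 1L
    spec$dih_target <- rep(deg2rad(rt$target), nsub)
    spec$dih_tol <- rep(deg2rad(rt$tol), nsub)
    spec$k_dih <- config$k_dih
  }
  if (!is.null(restraints) && length(restraints) > 0 && config$k_dist > 0) {
    base <- if (is_assembly) x$subunits[[1]]$atoms else atoms
    rr <- resolve_restraints(restraints, base)
    pairs <- do.call(rbind, lapply(seq_len(nsub) - 1L,
                                   function(m) rr$pairs + m * per))
    npair1 <- nrow(rr$pairs)
    offs <- unlist(lapply(seq_len(nsub) - 1L,
                          function(m) rr$offsets[-length(rr$offsets)] +
                            m * npair1))
    offs <- c(offs, nsub * npair1)
    spec$dr_pairs <- pairs - 1L
    spec$dr_offset <- as.integer(offs)
    spec$dr_lower <- rep(rr$lower, nsub)
    spec$dr_upper <- rep(rr$upper, nsub)
    spec$k_dist <- config$k_dist
  }
  if (is_assembly && nsub >= 2 && config$k_ncs > 0) {
    spec$ncs_idx <- do.call(rbind, lapply(sub_idx, function(v)
      as.integer(v - 1L)))
    spec$k_ncs <- config$k_ncs
    spec$ncs_tol <- config$tol_ncs
  }
  if (!is.null(map) && config$k_map > 0) {
    spec$map <- map_spec(map, config$map_threshold)
    sel <- which(atoms$atom %in% selection_atom_names(config$map_selection))
    if (!is.null(config$map_residue_mask))
      sel <- sel[atoms$resi[sel] %in% config$map_residue_mask]
    if (length(sel) == 0) stop("map selection matches no atoms")
    spec$map_sel <- as.integer(sel - 1L)
    spec$k_map <- config$k_map
  }
  if (config$k_repel > 0) {
    spec$k_repel <- config$k_repel
    spec$r_repel <- config$r_repel
    spec$excl <- excluded_pairs(topology) - 1L
  }
  k_rgyr <- config$k_rgyr
  if (!is.null(map) && config$k_map > 0 && k_rgyr > 0) {
    # the gyration-volume surrogate conflicts with the density potential
    k_rgyr <- 0
  }
  if (k_rgyr > 0) {
    spec$k_rgyr <- k_rgyr
    X0 <- as.matrix(atoms[, c("x", "y", "z")])
    tgt <- config$rgyr_target
    if (is.na(tgt))
      tgt <- sqrt(mean(rowSums(sweep(X0, 2, colMeans(X0))^2)))
    spec$rgyr_target <- tgt
  }
  structure(list(x = x, atoms = atoms, topology = topology, spec = spec,
                 masses = element_mass(atoms$elem), n = n, nsub = nsub,
                 per_subunit = per, sub_idx = sub_idx,
                 is_assembly = is_assembly, restraints = restraints,
                 torsions = torsions, map = map, config = config),
            class = "nmrem_system")
}

empty_topology <- function() {
  list(bonds = data.frame(i = integer(0), j = integer(0), r0 = numeric(0)),
       angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           th0 = numeric(0)),
       impropers = data.frame(i = integer(0), j = integer(0), k = integer(0),
                              l = integer(0), phi0 = numeric(0)))
}

selection_atom_names <- function(sel) {
  if (identical(sel, "backbone")) return(BACKBONE_ATOMS)
  if (startsWith(sel, "name ")) return(strsplit(sub("name ", "", sel), ",")[[1]])
  if (identical(sel, "heavy")) return(unique(c(BACKBONE_ATOMS, SIDE_NAMES)))
  stop("unsupported map selection: ", sel)
}

# 1-2 and 1-3 bonded pairs (from bonds and angle endpoints), 1-based
excluded_pairs <- function(topology) {
  p <- rbind(as.matrix(topology$bonds[, c("i", "j")]),
             as.matrix(topology$angles[, c("i", "k")]))
  if (nrow(p) == 0) return(matrix(0L, 0, 2))
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  storage.mode(p) <- "integer"
  unique(p)
}

#' @export
print.nmrem_system <- function(x, ...) {
  cat(sprintf("<energy system: %d atoms (%d subunit%s)>\n", x$n, x$nsub,
              if (x$nsub > 1) "s" else ""))
  terms <- intersect(c("bonds", "dihres", "dr_pairs", "ncs_idx", "map"),
                     names(x$spec))
  cat("  terms:", paste(terms, collapse = ", "), "\n")
  invisible(x)
}

system_coords <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

# write updated coordinates back into the structure/assembly
system_with_coords <- function(system, X) {
  system$atoms$x <- X[, 1]; system$atoms$y <- X[, 2]; system$atoms$z <- X[, 3]
  if (system$is_assembly) {
    for (m in seq_along(system$x$subunits)) {
      idx <- system$sub_idx[[m]]
      coords(system$x$subunits[[m]]) <- X[idx, , drop = FALSE]
    }
  } else {
    coords(system$x) <- X
  }
  system
}

#' Total energy and per-term breakdown
#'
#' @param system an `nmrem_system`
#' @param coords optional n x 3 coordinates (defaults to the system's)
#' @param gradient return the per-atom gradient
#' @return list of class `nmrem_energy`: `terms` (named, kcal/mol), `total`,
#'   and (optionally) `gradient` (kcal/mol/A)
#' @export
total_energy <- function(system, coords = NULL, gradient = TRUE) {
  X <- if (is.null(coords)) system_coords(system) else coords
  out <- cpp_energy(X, system$spec, gradient)
  structure(out, class = "nmrem_energy")
}

#' @export
print.nmrem_energy <- function(x, ...) {
  nz <- x$terms[x$terms != 0 | names(x$terms) %in%
                  c("bond", "distance", "map")]
  cat(sprintf("total energy: %.3f kcal/mol\n", x$total))
  for (nm in names(nz)) cat(sprintf("  %-9s %12.4f\n", nm, nz[[nm]]))
  invisible(x)
}

# ---- single-term convenience wrappers -------------------------------------

#' Flat-bottom (ambiguous) distance-restraint energy
#'
#' Per restraint the effective distance is the r^-6 sum over candidate pairs,
#' `(sum_p d_p^-6)^(-1/6)`; the energy is `k (d_eff - U)^2` above the upper
#' bound, `k (L - d_eff)^2` below the lower bound, and zero inside.
#'
#' @param x a structure
#' @param restraints `nmrem_restraints`
#' @param k force constant (kcal/mol/A^2)
#' @return `nmrem_energy` with only the distance term active
#' @export
distance_energy <- function(x, restraints, k = 30) {
  rr <- resolve_restraints(restraints, x$atoms)
  spec <- list(dr_pairs = rr$pairs - 1L, dr_offset = as.integer(rr$offsets),
               dr_lower = rr$lower, dr_upper = rr$upper, k_dist = k)
  structure(cpp_energy(coords(x), spec, TRUE), class = "nmrem_energy")
}

#' Dihedral (torsion) restraint energy
#'
#' Quadratic penalty (in radians) on the wrapped deviation beyond the
#' per-restraint tolerance.
#'
#' @param x a structure
#' @param torsions torsion data.frame (`resi`, `angle`, `target`,
#'   `tolerance` in degrees)
#' @param k force constant (kcal/mol/rad^2)
#' @export
dihedral_energy <- function(x, torsions, k = 200) {
  rt <- resolve_torsions(torsions, x$atoms)
  spec <- list(dihres = rt$quads - 1L, dih_target = deg2rad(rt$target),
               dih_tol = deg2rad(rt$tol), k_dih = k)
  structure(cpp_energy(coords(x), spec, TRUE), class = "nmrem_energy")
}

#' Covalent-geometry energy (bonds, angles, impropers)
#' @param x a structure with populated topology
#' @param config force constants
#' @export
covalent_energy <- function(x, config = energy_config()) {
  top <- x$topology
  if (is.null(top) || nrow(top$bonds) == 0) stop("structure has no topology")
  spec <- list(bonds = as.matrix(top$bonds[, c("i", "j")]) - 1L,
               bond_r0 = top$bonds$r0, k_bond = config$k_bond,
               angles = as.matrix(top$angles[, c("i", "j", "k")]) - 1L,
               angle_t0 = deg2rad(top$angles$th0), k_angle = config$k_angle,
               impropers = as.matrix(top$impropers[, c("i", "j", "k", "l")]) - 1L,
               impr_t0 = deg2rad(top$impropers$phi0),
               k_impr = config$k_improper)
  structure(cpp_energy(coords(x), spec, TRUE), class = "nmrem_energy")
}

#' Non-crystallographic-symmetry similarity energy
#'
#' For every pair of subunits, the pair is optimally superposed and the RMSD
#' excess over `tolerance` is penalized quadratically; zero when all pairs
#' agree within tolerance, and invariant under rigid motion of any subunit.
#'
#' @param assembly an `nmrem_assembly` (>= 2 subunits, identical atom order)
#' @param tolerance allowed pairwise RMSD (A)
#' @param k force constant (kcal/mol/A^2)
#' @export
ncs_energy <- function(assembly, tolerance = 1.0, k = 100) {
  if (!inherits(assembly, "nmrem_assembly") || length(assembly$subunits) < 2)
    stop("need an assembly with at least 2 subunits")
  check_matching_atoms(assembly$subunits)
  per <- nrow(assembly$subunits[[1]]$atoms)
  nsub <- length(assembly$subunits)
  idx <- do.call(rbind, lapply(seq_len(nsub) - 1L,
                               function(m) as.integer(m * per + 0:(per - 1))))
  X <- do.call(rbind, lapply(assembly$subunits, coords))
  spec <- list(ncs_idx = idx, k_ncs = k, ncs_tol = tolerance)
  structure(cpp_energy(X, spec, TRUE), class = "nmrem_energy")
}

#' Density-map cross-correlation energy
#'
#' `E = k (1 - CC)` where CC is the real-space cross-correlation between the
#' simulated density of the selected atoms and the target map over the
#' target-derived mask.
#'
#' @param x structure or assembly
#' @param map an `nmrem_map`
#' @param k force constant (kcal/mol)
#' @param selection atom selection (default backbone N, C', CA, O)
#' @param residue_mask residue indices included (NULL = all)
#' @export
map_energy <- function(x, map, k = 50, selection = "backbone",
                       residue_mask = NULL) {
  cfg <- energy_config(k_map = k, map_selection = selection,
                       map_residue_mask = residue_mask,
                       k_bond = 0, k_angle = 0, k_improper = 0, k_repel = 0)
  sys <- make_system(x, map = map, config = cfg)
  total_energy(sys)
}
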