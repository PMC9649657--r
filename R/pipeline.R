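# Four-stage protocol orchestration: (1) restrained annealing of a single
# chain inside a low-resolution envelope; (2) multi-position rigid-body
# docking into the experimental map; (3) joint NCS-restrained refinement of
# the multi-copy assembly against the map; (4) localized refinement of the
# mobile neck-linker segment with the core held rigid; plus ensemble
# validation and the alternative-start convergence check.

#' Pipeline configuration
#'
#' Defaults mirror the reference protocol: 100 annealed structures for the
#' single-chain and joint stages, 1000 per subunit for the neck-linker stage,
#' 22 subunits, free range 321-349, an 8 A envelope for stage 1. Toy runs
#' override these with smaller numbers and a reduced schedule.
#'
#' @param n_structures_stage1,n_structures_stage3,n_per_subunit batch sizes
#' @param n_subunits number of docked copies
#' @param free_range residue range allowed to move in stage 4
#' @param envelope_resolution stage-1 synthetic envelope resolution (A)
#' @param map_residue_mask residues entering the map term (NULL = all)
#' @param schedule an [build_schedule()] result
#' @param energy an [energy_config()]
#' @param rotation_samples docking rotation-set size
#' @param seed base seed
#' @return list of class `nmrem_pipeline_config`
#' @export
pipeline_config <- function(n_structures_stage1 = 100,
                            n_structures_stage3 = 100,
                            n_per_subunit = 1000,
                            n_subunits = 22,
                            free_range = c(321, 349),
                            envelope_resolution = 8,
                            map_residue_mask = NULL,
                            schedule = build_schedule(),
                            energy = energy_config(),
                            rotation_samples = 500,
                            seed = 1) {
  if (n_subunits < 1) stop("n_subunits must be >= 1")
  structure(list(n_structures_stage1 = n_structures_stage1,
                 n_structures_stage3 = n_structures_stage3,
                 n_per_subunit = n_per_subunit, n_subunits = n_subunits,
                 free_range = free_range,
                 envelope_resolution = envelope_resolution,
                 map_residue_mask = map_residue_mask, schedule = schedule,
                 energy = energy, rotation_samples = rotation_samples,
                 seed = seed),
            class = "nmrem_pipeline_config")
}

# translate a structure so its center of mass sits on the map's density
# centroid (keeps restrained dynamics inside the envelope)
center_on_map <- function(structure, map) {
  g <- as.numeric(map$grid)
  d <- dim(map$grid)
  w <- pmax(g, 0)
  idx <- arrayInd(seq_along(g), d) - 1
  centroid <- colSums(idx * w) / sum(w) * map$voxel + map$origin
  X <- coords(structure)
  coords(structure) <- sweep(X, 2, colMeans(X) - centroid)
  structure
}

stage_energy_config <- function(config, for_map = TRUE) {
  cfg <- config$energy
  if (for_map) cfg$map_residue_mask <- config$map_residue_mask
  cfg
}

#' Stage 1: restrained annealing of a single chain
#'
#' Anneals `n_structures_stage1` copies under distance, dihedral, covalent
#' and envelope-map terms (map restricted to backbone atoms so sidechain
#' orientations stay defined by the NMR restraints) and returns the
#' lowest-energy chain. When no envelope is supplied, a synthetic one is
#' simulated from the start coordinates at `envelope_resolution`.
#'
#' @param start_structure starting coordinates (chain already extended over
#'   the restrained residues; see [extend_chain()])
#' @param restraints `nmrem_restraints`
#' @param torsions torsion data.frame
#' @param envelope_map optional `nmrem_map`
#' @param config a [pipeline_config()]
#' @return list with `structure` (lowest energy), `batch`, `envelope`
#' @export
stage1_single_chain <- function(start_structure, restraints, torsions,
                                envelope_map = NULL,
                                config = pipeline_config()) {
  if (is.null(envelope_map)) {
    envelope_map <- simulate_map(start_structure,
                                 resolution = config$envelope_resolution,
                                 voxel = config$envelope_resolution / 3)
  } else {
    start_structure <- center_on_map(start_structure, envelope_map)
  }
  sys <- make_system(start_structure, restraints, torsions, envelope_map,
                     stage_energy_config(config))
  batch <- run_batch(sys, config$schedule, config$n_structures_stage1,
                     base_seed = config$seed)
  list(structure = batch[[1]]$structure, batch = batch,
       envelope = envelope_map)
}

#' Stage 2: multi-position docking into the experimental map
#'
#' @param chain refined single chain (stage-1 output)
#' @param experimental_map target `nmrem_map`
#' @param n number of positions (default `config$n_subunits`)
#' @param config a [pipeline_config()]
#' @return list with `placements`, `copies` (transformed structures) and
#'   `table` (score TSV content, descending)
#' @export
stage2_dock <- function(chain, experimental_map, n = NULL,
                        config = pipeline_config()) {
  if (is.null(n)) n <- config$n_subunits
  placements <- dock_positions(chain, experimental_map, n_positions = n,
                               rotation_samples = config$rotation_samples)
  copies <- lapply(placements, function(p) apply_placement(chain, p))
  list(placements = placements, copies = copies,
       table = placements_table(placements))
}

#' Stage 3: joint NCS-restrained refinement of the assembly
#'
#' Replicates the chain into the docked positions, applies the full restraint
#' set to every subunit, couples the subunits with the NCS similarity term
#' (tolerance 1 A), adds the map term over the whole assembly, anneals and
#' minimizes; the lowest-energy assembly is returned.
#'
#' @param chain refined single chain
#' @param placements stage-2 placements (one per subunit)
#' @param restraints,torsions per-subunit restraints
#' @param experimental_map target map
#' @param config a [pipeline_config()]
#' @return list with `assembly` (lowest energy) and `batch`
#' @export
stage3_joint_refine <- function(chain, placements, restraints, torsions,
                                experimental_map,
                                config = pipeline_config()) {
  nsub <- length(placements)
  asm <- replicate_subunits(chain, nsub)
  for (k in seq_len(nsub))
    asm$subunits[[k]] <- apply_placement(asm$subunits[[k]], placements[[k]])
  sys <- make_system(asm, restraints, torsions, experimental_map,
                     stage_energy_config(config))
  batch <- run_batch(sys, config$schedule, config$n_structures_stage3,
                     base_seed = config$seed + 1000L)
  best <- batch[[1]]
  list(assembly = best$system$x, batch = batch)
}

#' Stage 4: localized neck-linker refinement
#'
#' Per subunit, anneals `n_per_subunit` structures in which residues outside
#' `free_range` move only as one rigid body (6 degrees of freedom) while the
#' free range is fully mobile, picks the lowest-energy conformer, realigns it
#' onto the stage-3 pose by superposing the rigid residues, and (when a map is
#' given) locally refits it to the density.
#'
#' @param assembly stage-3 assembly
#' @param extra_restraints additional restraints for the free range (appended
#'   to `restraints`)
#' @param restraints,torsions the stage-1 restraint set (may be NULL)
#' @param free_range mobile residue range
#' @param n_per_subunit batch size per subunit
#' @param experimental_map optional map for the final local refit
#' @param config a [pipeline_config()]
#' @return list with `assembly` (final ensemble, one conformer per subunit)
#'   and `batches`
#' @export
stage4_neck_linker <- function(assembly, extra_restraints = NULL,
                               restraints = NULL, torsions = NULL,
                               free_range = NULL, n_per_subunit = NULL,
                               experimental_map = NULL,
                               config = pipeline_config()) {
  if (is.null(free_range)) free_range <- config$free_range
  if (is.null(n_per_subunit)) n_per_subunit <- config$n_per_subunit
  all_restraints <- concat_restraints(restraints, extra_restraints)
  nsub <- length(assembly$subunits)
  out <- assembly
  batches <- vector("list", nsub)
  for (k in seq_len(nsub)) {
    sub <- assembly$subunits[[k]]
    sys <- make_system(sub, all_restraints, torsions, experimental_map,
                       stage_energy_config(config))
    free_sel <- sprintf("resi %d-%d", free_range[1], free_range[2])
    free_idx <- select_atoms(sub, free_sel)
    rigid_idx <- setdiff(seq_len(nrow(sub$atoms)), free_idx)
    batch <- tryCatch(
      run_batch(sys, config$schedule, n_per_subunit,
                base_seed = config$seed + 2000L + k * n_per_subunit,
                free_idx = seq_len(nrow(sub$atoms)),
                rigid_idx = rigid_idx),
      error = function(e) {
        warning("subunit ", k, ": all refinement runs failed (",
                conditionMessage(e), "); keeping the joint-refinement pose")
        NULL
      })
    if (is.null(batch)) {
      out$subunits[[k]] <- sub
      batches[[k]] <- list()
      next
    }
    best <- batch[[1]]$structure
    # realign the rigid core onto the stage-3 pose
    core_sel <- paste("backbone resi",
                      paste(range(setdiff(unique(sub$atoms$resi),
                                          seq(free_range[1], free_range[2]))),
                            collapse = "-"))
    fit <- superpose(sub, best, core_sel)
    best <- fit$transformed
    if (!is.null(experimental_map)) {
      pl <- local_fit(best, experimental_map,
                      new_placement(diag(3), c(0, 0, 0)))
      best <- apply_placement(best, pl)
    }
    best$atoms$chain <- assembly$segment_ids[k]
    out$subunits[[k]] <- best
    batches[[k]] <- batch
  }
  list(assembly = out, batches = batches)
}

concat_restraints <- function(a, b) {
  out <- c(unclass(a %||% list()), unclass(b %||% list()))
  structure(out, class = "nmrem_restraints")
}

# effective (r^-6 summed) distances of all restraints in one conformer
eff_distances <- function(structure, restraints) {
  rr <- resolve_restraints(restraints, structure$atoms)
  X <- coords(structure)
  vapply(seq_along(restraints), function(k) {
    rows <- (rr$offsets[k] + 1):rr$offsets[k + 1]
    d <- sqrt(rowSums((X[rr$pairs[rows, 1], , drop = FALSE] -
                       X[rr$pairs[rows, 2], , drop = FALSE])^2))
    sum(d^-6)^(-1 / 6)
  }, 0)
}

torsion_violations <- function(structure, torsions) {
  tor <- validate_torsions(torsions)
  meas <- measure_torsions(structure)
  obs <- ifelse(tor$angle == "phi",
                meas$phi[match(tor$resi, meas$resi)],
                meas$psi[match(tor$resi, meas$resi)])
  dev <- abs(wrap_angle(obs - tor$target))
  pmax(0, dev - tor$tolerance)
}

#' Ensemble validation report
#'
#' Violation statistics are computed per conformer and pooled across the
#' ensemble (mean +/- sd). The mean distance (dihedral) violation is the mean
#' magnitude over restraints exceeding their bounds (tolerance); ambiguous
#' restraints use the r^-6-averaged effective distance.
#'
#' @param ensemble list of structures, or an assembly
#' @param restraints `nmrem_restraints`
#' @param torsions torsion data.frame (optional)
#' @return object of class `nmrem_validation`
#' @export
validate <- function(ensemble, restraints, torsions = NULL) {
  if (inherits(ensemble, "nmrem_assembly")) ensemble <- ensemble$subunits
  if (inherits(ensemble, "nmrem_structure")) ensemble <- list(ensemble)
  if (length(ensemble) == 0) stop("empty ensemble")
  lo <- vapply(restraints, `[[`, 0, "lower")
  hi <- vapply(restraints, `[[`, 0, "upper")
  per <- lapply(ensemble, function(s) {
    d <- eff_distances(s, restraints)
    viol <- pmax(0, d - hi, lo - d)
    dv <- if (!is.null(torsions)) torsion_violations(s, torsions)
          else numeric(0)
    list(mean_dist = if (any(viol > 0)) mean(viol[viol > 0]) else 0,
         max_dist = if (length(viol)) max(viol) else 0,
         mean_dih = if (any(dv > 0)) mean(dv[dv > 0]) else 0,
         max_dih = if (length(dv)) max(dv) else 0,
         geom = tryCatch(geometry_deviations(s),
                         error = function(e) c(bond = NA, angle = NA,
                                               improper = NA)))
  })
  g <- function(f) vapply(per, f, 0)
  geom <- t(vapply(per, `[[`, c(bond = 0, angle = 0, improper = 0), "geom"))
  rmsd_bb <- rmsd_heavy <- NULL
  if (length(ensemble) >= 2) {
    rmsd_bb <- pairwise_ensemble_rmsd(ensemble, "backbone")
    rmsd_heavy <- pairwise_ensemble_rmsd(ensemble, "heavy")
  }
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  structure(list(
    summary = summarize_restraints(restraints, torsions,
                                   n_residues(ensemble[[1]])),
    n_conformers = length(ensemble),
    dist_violation_mean = mean(g(function(p) p$mean_dist)),
    dist_violation_sd = sd0(g(function(p) p$mean_dist)),
    dist_violation_max = max(g(function(p) p$max_dist)),
    dih_violation_mean = mean(g(function(p) p$mean_dih)),
    dih_violation_sd = sd0(g(function(p) p$mean_dih)),
    dih_violation_max = max(g(function(p) p$max_dih)),
    geometry_mean = colMeans(geom),
    geometry_sd = apply(geom, 2, sd0),
    rmsd_backbone = rmsd_bb, rmsd_heavy = rmsd_heavy),
    class = "nmrem_validation")
}

#' @export
print.nmrem_validation <- function(x, ...) {
  cat(sprintf("Structure statistics (%d conformers)\n", x$n_conformers))
  cat("Violations (mean +/- s.d.)\n")
  cat(sprintf("  Distance restraints (A)   %.3f +/- %.3f\n",
              x$dist_violation_mean, x$dist_violation_sd))
  cat(sprintf("  Dihedral restraints (deg) %.3f +/- %.3f\n",
              x$dih_violation_mean, x$dih_violation_sd))
  cat(sprintf("  Max distance violation (A)   %.3f\n", x$dist_violation_max))
  cat(sprintf("  Max dihedral violation (deg) %.3f\n", x$dih_violation_max))
  cat("Deviations from idealized geometry (mean +/- s.d.)\n")
  cat(sprintf("  Bond lengths (A) %.4f +/- %.4f\n",
              x$geometry_mean["bond"], x$geometry_sd["bond"]))
  cat(sprintf("  Bond angles (deg) %.3f +/- %.3f\n",
              x$geometry_mean["angle"], x$geometry_sd["angle"]))
  cat(sprintf("  Impropers (deg)   %.3f +/- %.3f\n",
              x$geometry_mean["improper"], x$geometry_sd["improper"]))
  if (!is.null(x$rmsd_backbone)) {
    cat("Average pairwise r.m.s.d. (A)\n")
    cat(sprintf("  Backbone (N, CA, C) %.3f +/- %.3f\n",
                x$rmsd_backbone$mean, x$rmsd_backbone$sd))
    cat(sprintf("  Heavy               %.3f +/- %.3f\n",
                x$rmsd_heavy$mean, x$rmsd_heavy$sd))
  }
  invisible(x)
}

#' Write a validation report as TSV and text
#' @param report an `nmrem_validation`
#' @param path_tsv,path_txt output paths (NULL to skip)
#' @export
write_validation <- function(report, path_tsv = NULL, path_txt = NULL) {
  if (!is.null(path_tsv)) {
    df <- data.frame(
      statistic = c("dist_violation_mean", "dist_violation_sd",
                    "dist_violation_max", "dih_violation_mean",
                    "dih_violation_sd", "dih_violation_max",
                    "bond_rmsd", "angle_rmsd", "improper_rmsd",
                    "rmsd_backbone_mean", "rmsd_heavy_mean"),
      value = c(report$dist_violation_mean, report$dist_violation_sd,
                report$dist_violation_max, report$dih_violation_mean,
                report$dih_violation_sd, report$dih_violation_max,
                report$geometry_mean["bond"], report$geometry_mean["angle"],
                report$geometry_mean["improper"],
                report$rmsd_backbone$mean %||% NA,
                report$rmsd_heavy$mean %||% NA))
    write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_txt)) {
    con <- file(path_txt, "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(report)
}

#' Alternative-start convergence validation
#'
#' Runs stage 1 from each start model and reports the pairwise backbone RMSD
#' between the final structures, between the starts, and start-vs-final per
#' run. Convergence means the finals are mutually closer than their distinct
#' starts were.
#'
#' @param start_models list of >= 2 structures with one sequence
#' @param restraints,torsions restraint set
#' @param map optional envelope/experimental map
#' @param config a [pipeline_config()]
#' @return list with `final_rmsd` (matrix), `start_rmsd` (matrix),
#'   `start_vs_final` (vector), `finals`, `converged`
#' @export
validate_alternative_starts <- function(start_models, restraints, torsions,
                                        map = NULL,
                                        config = pipeline_config()) {
  if (length(start_models) < 2) stop("need at least 2 start models")
  seqs <- vapply(start_models, `[[`, "", "sequence")
  if (length(unique(seqs)) != 1)
    stop("start models differ in sequence")
  finals <- vector("list", length(start_models))
  for (k in seq_along(start_models)) {
    cfgk <- config
    cfgk$seed <- config$seed + (k - 1) * 131L
    finals[[k]] <- stage1_single_chain(start_models[[k]], restraints,
                                       torsions, map, cfgk)$structure
  }
  pm <- function(lst) {
    n <- length(lst)
    M <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      M[i, j] <- M[j, i] <- superpose(lst[[i]], lst[[j]], "name N,CA,C")$rmsd
    M
  }
  fin_m <- pm(finals)
  sta_m <- pm(start_models)
  svf <- vapply(seq_along(finals), function(k)
    superpose(start_models[[k]], finals[[k]], "name N,CA,C")$rmsd, 0)
  ut <- upper.tri(fin_m)
  list(final_rmsd = fin_m, start_rmsd = sta_m, start_vs_final = svf,
       finals = finals,
       converged = max(fin_m[ut]) < max(sta_m[ut]))
}

#' Run the full four-stage pipeline on explicit inputs
#'
#' Thin orchestration over [stage1_single_chain()], [stage2_dock()],
#' [stage3_joint_refine()] and [stage4_neck_linker()], returning every
#' intermediate plus a final [validate()] report.
#'
#' @param start_structure starting chain
#' @param restraints,torsions restraint set
#' @param experimental_map target density map
#' @param extra_restraints stage-4 restraints (optional)
#' @param config a [pipeline_config()]
#' @param out_dir optional directory for ensemble PDB, placement TSV and
#'   validation report
#' @return list with per-stage results and `report`
#' @export
run_pipeline <- function(start_structure, restraints, torsions,
                         experimental_map, extra_restraints = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  s1 <- stage1_single_chain(start_structure, restraints, torsions,
                            config = config)
  s2 <- stage2_dock(s1$structure, experimental_map, config$n_subunits,
                    config)
  s3 <- stage3_joint_refine(s1$structure, s2$placements, restraints,
                            torsions, experimental_map, config)
  s4 <- stage4_neck_linker(s3$assembly, extra_restraints, restraints,
                           torsions, experimental_map = experimental_map,
                           config = config)
  report <- validate(s4$assembly, concat_restraints(restraints,
                                                    extra_restraints),
                     torsions)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_structure(s4$assembly$subunits,
                    file.path(out_dir, "ensemble.pdb"))
    write_placements(s2$placements, file.path(out_dir, "placements.tsv"))
    write_validation(report, file.path(out_dir, "validation.tsv"),
                     file.path(out_dir, "validation.txt"))
  }
  list(stage1 = s1, stage2 = s2, stage3 = s3, stage4 = s4, report = report)
}
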