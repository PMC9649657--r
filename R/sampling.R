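# Restrained simulated annealing: Cartesian velocity-Verlet dynamics with a
# velocity-rescaling thermostat, an adaptive timestep that halves whenever a
# step breaks energy conservation (2% of total energy per step by default),
# temperature-coupled force-constant ramps, and gradient minimization.

#' Build an annealing schedule
#'
#' The default schedule mirrors the reference protocol: two high-temperature
#' stages at 3000 K (10 ps or 10,000 steps, whichever completes first),
#' followed by cooling from 3000 K to 25 K in steps of 25 K with a 0.4 ps
#' stage at each temperature. The distance-restraint force constant ramps
#' linearly from 2 to 30 kcal/mol/A^2 across the cooling stages; the dihedral
#' force constant is 10 kcal/mol/rad^2 at high temperature and 200 during
#' cooling; the map force constant is held at 50 kcal/mol throughout.
#'
#' @param config named list overriding defaults: `high_T`, `n_high_stages`,
#'   `high_duration_ps`, `high_max_steps`, `T_start`, `T_end`, `decrement`,
#'   `per_T_duration_ps`, `k_dist_ramp` (length 2), `k_dih_high`,
#'   `k_dih_cool`, `k_map`, `initial_timestep_fs`
#' @param strict when TRUE (default) a decrement that does not divide the
#'   cooling range is a configuration error; when FALSE a terminal stage at
#'   `T_end` is appended instead
#' @return object of class `nmrem_schedule`
#' @export
build_schedule <- function(config = list(), strict = TRUE) {
  def <- list(high_T = 3000, n_high_stages = 2, high_duration_ps = 10,
              high_max_steps = 10000, T_start = 3000, T_end = 25,
              decrement = 25, per_T_duration_ps = 0.4,
              k_dist_ramp = c(2, 30), k_dih_high = 10, k_dih_cool = 200,
              k_map = 50, initial_timestep_fs = 1)
  for (nm in names(config)) def[[nm]] <- config[[nm]]
  with(def, {
    if (T_end >= T_start) stop("T_end must be below T_start")
    if (strict && (T_start - T_end) %% decrement != 0)
      stop("decrement must divide the cooling range")
    if (per_T_duration_ps <= 0 || high_duration_ps <= 0)
      stop("stage durations must be positive")
  })
  temps <- seq(def$T_start, def$T_end, by = -def$decrement)
  if (temps[length(temps)] > def$T_end) temps <- c(temps, def$T_end)
  ncool <- length(temps)
  kd <- if (ncool > 1)
    def$k_dist_ramp[1] + (def$k_dist_ramp[2] - def$k_dist_ramp[1]) *
      (seq_len(ncool) - 1) / (ncool - 1)
  else def$k_dist_ramp[2]
  stages <- rbind(
    if (def$n_high_stages > 0)
      data.frame(phase = "high", temperature = def$high_T,
                 duration_ps = def$high_duration_ps,
                 max_steps = def$high_max_steps,
                 k_dist = def$k_dist_ramp[1], k_dih = def$k_dih_high,
                 k_map = def$k_map)[rep(1, def$n_high_stages), ]
    else NULL,
    data.frame(phase = "cool", temperature = temps,
               duration_ps = def$per_T_duration_ps,
               max_steps = ceiling(def$per_T_duration_ps /
                                     (def$initial_timestep_fs * 1e-3)) * 10L,
               k_dist = kd, k_dih = def$k_dih_cool, k_map = def$k_map))
  rownames(stages) <- NULL
  structure(list(stages = stages, initial_timestep_fs =
                   def$initial_timestep_fs, params = def),
            class = "nmrem_schedule")
}

#' @export
print.nmrem_schedule <- function(x, ...) {
  st <- x$stages
  nh <- sum(st$phase == "high"); nc <- sum(st$phase == "cool")
  cat(sprintf(
    "<annealing schedule: %d high-T stage(s) at %g K, %d cooling stages %g -> %g K>\n",
    nh, if (nh) st$temperature[1] else NA, nc,
    if (nc) max(st$temperature[st$phase == "cool"]) else NA,
    if (nc) min(st$temperature[st$phase == "cool"]) else NA))
  cat(sprintf("  k_dist ramp %g -> %g; k_dih %g (high) / %g (cool); k_map %g\n",
              x$params$k_dist_ramp[1], x$params$k_dist_ramp[2],
              x$params$k_dih_high, x$params$k_dih_cool, x$params$k_map))
  invisible(x)
}

#' Maxwell-Boltzmann initial velocities
#'
#' Per-component Gaussian velocities at the target temperature,
#' `v ~ N(0, kB T / m)` per degree of freedom. Reproducible under a fixed
#' seed.
#'
#' @param x structure, system, or a numeric vector of atomic masses (amu)
#' @param temperature target temperature (K)
#' @param seed RNG seed
#' @return n x 3 velocity matrix (A/ps)
#' @export
maxwell_velocities <- function(x, temperature, seed = 1) {
  masses <- if (inherits(x, "nmrem_system")) x$masses
            else if (is.numeric(x)) x
            else atom_masses(x)
  n <- length(masses)
  set.seed(seed)
  if (temperature <= 0) return(matrix(0, n, 3))
  sdv <- sqrt(418.4 * KB_KCAL * temperature / masses)
  matrix(rnorm(3 * n), n, 3) * sdv
}

measured_temperature <- function(vel, masses, ndof = NULL) {
  ek <- sum(0.5 * masses * rowSums(vel^2)) / 418.4
  if (is.null(ndof)) ndof <- 3 * length(masses)
  2 * ek / (KB_KCAL * ndof)
}

#' Run one thermostatted dynamics stage
#'
#' Velocity-Verlet integration with a velocity-rescaling thermostat and an
#' energy-conservation-guarded adaptive timestep (halved down to 0.1 fs when
#' one step changes the total energy by more than `econs_frac` of its
#' magnitude, gradually restored).
#'
#' @param system an `nmrem_system`
#' @param temperature target temperature (K); ignored if `thermostat = FALSE`
#' @param duration_ps stage duration (ps)
#' @param timestep_fs initial timestep (fs)
#' @param max_steps step cap
#' @param velocities n x 3 starting velocities (default: Maxwell at
#'   `temperature` under `seed`)
#' @param seed seed for velocity initialization when `velocities` is NULL
#' @param free_idx 1-based indices of mobile atoms (default all)
#' @param rigid_idx 1-based indices of atoms moving as one rigid body
#' @param econs_frac energy-conservation tolerance per step (fraction)
#' @param thermostat apply velocity rescaling
#' @return list with updated `system`, `velocities`, and a `summary` row
#' @export
dynamics_stage <- function(system, temperature, duration_ps,
                           timestep_fs = 1, max_steps = 100000,
                           velocities = NULL, seed = 1,
                           free_idx = NULL, rigid_idx = integer(0),
                           econs_frac = 0.02, thermostat = TRUE) {
  X <- system_coords(system)
  e0 <- cpp_energy(X, system$spec, FALSE)$total
  if (!is.finite(e0)) stop("non-finite starting energy")
  if (is.null(free_idx)) free_idx <- seq_len(system$n)
  free_idx <- setdiff(free_idx, rigid_idx)
  if (is.null(velocities))
    velocities <- maxwell_velocities(system, temperature, seed)
  res <- cpp_dynamics(X, velocities, system$masses, system$spec,
                      as.integer(free_idx - 1L),
                      as.integer(rigid_idx - 1L),
                      temperature, duration_ps, as.integer(max_steps),
                      timestep_fs, econs_frac, 10L, thermostat)
  system <- system_with_coords(system, res$coords)
  summary <- data.frame(temperature = temperature,
                        duration_ps = res$time_ps, nsteps = res$nsteps,
                        dt_final_fs = res$dt_final_fs,
                        n_halvings = res$n_halvings, epot = res$epot,
                        ekin = res$ekin, temp_measured = res$temperature,
                        failed = res$failed)
  list(system = system, velocities = res$vel, summary = summary)
}

#' Gradient minimization
#'
#' Minimizes the system's total energy over the free coordinates (L-BFGS-B;
#' the reference protocol names Powell minimization, any descent scheme
#' satisfying the energy-decrease and gradient-tolerance contract is
#' acceptable).
#'
#' @param system an `nmrem_system`
#' @param max_iter iteration cap
#' @param gtol gradient max-norm target (kcal/mol/A)
#' @param free 1-based indices of free atoms (default all)
#' @return list with minimized `system`, `structure`, `energy`, and
#'   `converged`
#' @export
minimize <- function(system, max_iter = 400, gtol = 1e-3, free = NULL) {
  X0 <- system_coords(system)
  if (!is.finite(cpp_energy(X0, system$spec, FALSE)$total))
    stop("non-finite starting energy")
  n <- system$n
  if (is.null(free)) free <- seq_len(n)
  fidx <- as.vector(outer(free, c(0, n, 2 * n), `+`)) # column-major slots
  xfull <- as.numeric(X0)
  fn <- function(p) {
    xfull[fidx] <- p
    cpp_energy(matrix(xfull, n, 3), system$spec, FALSE)$total
  }
  gr <- function(p) {
    xfull[fidx] <- p
    as.numeric(cpp_energy(matrix(xfull, n, 3), system$spec,
                          TRUE)$gradient)[fidx]
  }
  opt <- optim(xfull[fidx], fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = 1e4, pgtol = gtol))
  e0 <- fn(xfull[fidx])
  if (opt$value <= e0) xfull[fidx] <- opt$par
  Xm <- matrix(xfull, n, 3)
  system <- system_with_coords(system, Xm)
  en <- total_energy(system, gradient = TRUE)
  gmax <- max(abs(en$gradient[free, ]))
  list(system = system, structure = system$x, energy = en,
       converged = gmax <= gtol || opt$convergence == 0)
}

set_stage_constants <- function(system, k_dist, k_dih, k_map) {
  sp <- system$spec
  if (!is.null(sp$k_dist)) sp$k_dist <- k_dist
  if (!is.null(sp$k_dih)) sp$k_dih <- k_dih
  if (!is.null(sp$k_map)) sp$k_map <- k_map
  system$spec <- sp
  system
}

#' Restrained simulated annealing
#'
#' Executes the schedule's high-temperature stages followed by cooling with
#' ramped force constants, then a final minimization. Fully determined by
#' `(system, schedule, seed)`.
#'
#' @param system an `nmrem_system`
#' @param schedule an `nmrem_schedule`
#' @param seed RNG seed (velocity initialization)
#' @param free_idx,rigid_idx mobility control, as in [dynamics_stage()]
#' @return list of class `nmrem_run`: `structure`, `system`, `energy`,
#'   `seed`, `trajectory` (per-stage summary), `failed`
#' @export
anneal <- function(system, schedule, seed = 1, free_idx = NULL,
                   rigid_idx = integer(0)) {
  st <- schedule$stages
  vel <- NULL
  traj <- list()
  failed <- FALSE
  if (nrow(st) > 0) {
    vel <- maxwell_velocities(system, st$temperature[1], seed)
    for (s in seq_len(nrow(st))) {
      system <- set_stage_constants(system, st$k_dist[s], st$k_dih[s],
                                    st$k_map[s])
      out <- dynamics_stage(system, st$temperature[s], st$duration_ps[s],
                            timestep_fs = schedule$initial_timestep_fs,
                            max_steps = st$max_steps[s], velocities = vel,
                            free_idx = free_idx, rigid_idx = rigid_idx)
      system <- out$system
      vel <- out$velocities
      traj[[s]] <- cbind(stage = s, phase = st$phase[s], out$summary)
      if (out$summary$failed) { failed <- TRUE; break }
    }
    if (nrow(st) > 0 && !failed) {
      # leave force constants at their final (cooled) values for minimization
      system <- set_stage_constants(system, st$k_dist[nrow(st)],
                                    st$k_dih[nrow(st)], st$k_map[nrow(st)])
    }
  }
  min_free <- if (is.null(free_idx) && length(rigid_idx) == 0) NULL
              else setdiff(free_idx %||% seq_len(system$n), rigid_idx)
  mn <- minimize(system, free = min_free)
  structure(list(structure = mn$structure, system = mn$system,
                 energy = mn$energy, seed = seed,
                 trajectory = do.call(rbind, traj), failed = failed),
            class = "nmrem_run")
}

#' @export
print.nmrem_run <- function(x, ...) {
  cat(sprintf("<annealing run (seed %d): final energy %.3f kcal/mol%s>\n",
              x$seed, x$energy$total, if (x$failed) ", FAILED" else ""))
  invisible(x)
}

#' Batch of independent annealing runs
#'
#' Runs `n_structures` seeded annealing calculations and returns them sorted
#' by ascending final total energy (so index 1 is the lowest-energy
#' structure). Failed runs are excluded and counted.
#'
#' @param system an `nmrem_system` (or a factory `function(seed)` returning
#'   one, for randomized starts)
#' @param schedule an `nmrem_schedule`
#' @param n_structures number of runs
#' @param base_seed run `i` uses seed `base_seed + i - 1`
#' @param free_idx,rigid_idx mobility control
#' @return list of class `nmrem_batch` of `nmrem_run`, sorted by energy;
#'   attribute `n_failed`
#' @export
run_batch <- function(system, schedule, n_structures = 100, base_seed = 1,
                      free_idx = NULL, rigid_idx = integer(0)) {
  stopifnot(n_structures >= 1)
  runs <- vector("list", n_structures)
  for (i in seq_len(n_structures)) {
    sys_i <- if (is.function(system)) system(base_seed + i - 1) else system
    runs[[i]] <- tryCatch(
      anneal(sys_i, schedule, seed = base_seed + i - 1,
             free_idx = free_idx, rigid_idx = rigid_idx),
      error = function(e) {
        warning("run ", i, " failed: ", conditionMessage(e))
        NULL
      })
  }
  ok <- Filter(function(r) !is.null(r) && !r$failed, runs)
  n_failed <- n_structures - length(ok)
  if (length(ok) == 0) stop("all annealing runs failed")
  ord <- order(vapply(ok, function(r) r$energy$total, 0))
  structure(ok[ord], class = "nmrem_batch", n_failed = n_failed)
}

#' @export
print.nmrem_batch <- function(x, ...) {
  en <- vapply(x, function(r) r$energy$total, 0)
  cat(sprintf("<batch: %d runs, energies %.3f .. %.3f kcal/mol (%d failed)>\n",
              length(x), min(en), max(en), attr(x, "n_failed")))
  invisible(x)
}
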