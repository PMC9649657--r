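# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

# tiny ideal helix used across energy/dynamics tests
tiny_fold <- function(n = 10, spec = "helix", seed = 1) {
  make_toy_fold(n, spec, seed = seed)$structure
}

# a single-assignment peak row
peak_row <- function(exp_id, ri, ai, rj, aj, s1 = NA, s2 = NA, int = NA,
                     alt = "") {
  data.frame(exp_id = exp_id, res_i = ri, atom_i = ai, res_j = rj,
             atom_j = aj, shift1_ppm = s1, shift2_ppm = s2, intensity = int,
             alt_assignments = alt, stringsAsFactors = FALSE)
}

# restraint list from explicit (i, atom_i, j, atom_j) rows
restraints_from_pairs <- function(df, exp = "test") {
  peaks <- do.call(rbind, lapply(seq_len(nrow(df)), function(k)
    peak_row(exp, df$res_i[k], df$atom_i[k], df$res_j[k], df$atom_j[k])))
  peaks_to_restraints(peaks)
}

# random rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  v <- rnorm(3)
  nmrem:::rotvec_to_matrix(v / sqrt(sum(v^2)) * runif(1, 0.1, pi))
}

# max |analytic - finite difference| over sampled coordinates for a spec
fd_gradient_error <- function(X, spec, n_checks = 15, h = 1e-5, seed = 1) {
  g <- nmrem:::cpp_energy(X, spec, TRUE)$gradient
  set.seed(seed)
  maxrel <- 0
  for (t in seq_len(n_checks)) {
    i <- sample(nrow(X), 1); k <- sample(3, 1)
    Xp <- X; Xp[i, k] <- Xp[i, k] + h
    Xm <- X; Xm[i, k] <- Xm[i, k] - h
    fd <- (nmrem:::cpp_energy(Xp, spec, FALSE)$total -
           nmrem:::cpp_energy(Xm, spec, FALSE)$total) / (2 * h)
    denom <- max(abs(fd), abs(g[i, k]), 1e-4)
    maxrel <- max(maxrel, abs(fd - g[i, k]) / denom)
  }
  maxrel
}

# fast reduced annealing schedule for tests
test_schedule <- function(high_ps = 0.5, per_T = 0.2, decrement = 425) {
  build_schedule(list(high_duration_ps = high_ps, high_max_steps = 1000,
                      n_high_stages = 1, decrement = decrement,
                      per_T_duration_ps = per_T))
}
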