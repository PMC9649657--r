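# Cross-peak classification, bounds, deduplication, summaries and the
# two-state comparison.

test_that("contacts classify by sequence separation with strict medium range", {
  expect_equal(classify_contact(12, 12), "intra")
  expect_equal(classify_contact(44, 325), "long")
  expect_equal(classify_contact(10, 13), "medium")
  expect_equal(classify_contact(5, 6), "sequential")
  expect_equal(classify_contact(c(1, 2, 3), c(1, 3, 8)),
               c("intra", "sequential", "long"))
  # boundary: |i-j| = 4 is medium, 5 is long (strict convention)
  expect_equal(classify_contact(1, 5), "medium")
  expect_equal(classify_contact(1, 6), "long")
  expect_error(classify_contact(0, 3), "positive")
})

test_that("distance bounds match the published calibration", {
  expect_equal(unname(assign_bounds("intra")), c(1.5, 6.5, 4.0, 2.5))
  expect_equal(unname(assign_bounds("inter")), c(2.0, 7.2, 4.6, 2.6))
  for (cls in c("intra", "inter")) {
    b <- assign_bounds(cls)
    expect_equal(unname(b["upper"] - b["tolerance"]), unname(b["target"]))
  }
  expect_error(assign_bounds("weird"))
})

test_that("peaks convert to restraints with the ambiguity cap", {
  # 6 candidates with a limit of 5: dropped entirely
  p6 <- peak_row("cord", 1, "CA", 5, "CB",
                 alt = "2.CA-6.CB;3.CA-7.CB;4.CA-8.CB;1.CB-5.CA;2.CB-6.CA")
  r <- peaks_to_restraints(p6, ambiguity_limit = 5)
  expect_length(r, 0)
  expect_equal(attr(r, "dropped"), 1L)
  # same peak retained at limit 6
  expect_length(peaks_to_restraints(p6, ambiguity_limit = 6), 1)
  # single intra-residue assignment gets intra bounds
  r1 <- peaks_to_restraints(peak_row("cord", 3, "CA", 3, "CB"))
  expect_equal(r1[[1]]$lower, 1.5)
  expect_equal(r1[[1]]$upper, 6.5)
  expect_equal(r1[[1]]$category, "intra")
  # identical assignment from three experiments collapses to one restraint
  pk <- rbind(peak_row("e1", 2, "CA", 9, "CB"),
              peak_row("e2", 2, "CA", 9, "CB"),
              peak_row("e3", 9, "CB", 2, "CA"))
  r3 <- peaks_to_restraints(pk)
  expect_length(r3, 1)
  expect_equal(r3[[1]]$experiments, c("e1", "e2", "e3"))
  # mixed intra/inter ambiguity takes the looser inter bounds
  rmix <- peaks_to_restraints(peak_row("e1", 4, "CA", 4, "CB",
                                       alt = "4.CA-9.CB"))
  expect_equal(rmix[[1]]$category, "ambiguous")
  expect_equal(rmix[[1]]$upper, 7.2)
  # empty input
  expect_length(peaks_to_restraints(peak_row("e", 1, "CA", 2, "CB")[0, ]), 0)
})

test_that("deduplication is symmetric, idempotent, and counts correctly", {
  pk <- rbind(peak_row("e1", 10, "CA", 12, "CB"),
              peak_row("e1", 12, "CB", 10, "CA"))
  expect_length(peaks_to_restraints(pk), 1)
  # n unique + planted 20% duplicates -> 0.8 n survive
  set.seed(4)
  base <- data.frame(res_i = 1:20, atom_i = "CA",
                     res_j = 1:20 + sample(2:8, 20, TRUE), atom_j = "CB")
  dup <- base[1:5, c("res_j", "atom_j", "res_i", "atom_i")]
  names(dup) <- c("res_i", "atom_i", "res_j", "atom_j")
  r <- restraints_from_pairs(rbind(base, dup))
  expect_length(r, 20)
  expect_identical(assignments_of <- lapply(deduplicate(r), `[[`,
                                            "assignments"),
                   lapply(r, `[[`, "assignments"))
})

test_that("restraint summaries add up and fuzzed totals are conserved", {
  # torsion bookkeeping mirrors the published accounting shape
  tor <- rbind(data.frame(resi = 1:4, angle = "phi", target = -60,
                          tolerance = 20),
               data.frame(resi = 1:4, angle = "psi", target = -45,
                          tolerance = 20))
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    df <- data.frame(res_i = sample(1:40, n, TRUE), atom_i = "CA",
                     res_j = sample(1:40, n, TRUE), atom_j = "CB")
    r <- restraints_from_pairs(unique(df))
    s <- summarize_restraints(r, tor, n_residues = 40)
    expect_equal(s$total, s$unambiguous + s$ambiguous)
    expect_equal(s$inter, s$sequential + s$medium + s$long)
    expect_equal(s$unambiguous, s$intra + s$inter)
    expect_equal(s$torsion_total, s$phi + s$psi)
    expect_equal(s$restraints_per_residue, round(s$total / 40, 2))
  }
  # empty inputs give an all-zero summary
  s0 <- summarize_restraints(peaks_to_restraints(NULL), NULL, 10)
  expect_equal(s0$total, 0)
  expect_equal(s0$torsion_total, 0)
  expect_error(summarize_restraints(peaks_to_restraints(NULL), NULL, 0))
})

test_that("contact matrix is symmetric and balances the summary", {
  r <- restraints_from_pairs(data.frame(res_i = 10, atom_i = "CA",
                                        res_j = 15, atom_j = "CB"))
  M <- contact_matrix(r, 20)
  expect_equal(M[10, 15], 1)
  expect_equal(M[15, 10], 1)
  expect_equal(sum(M), 2)
  expect_equal(contact_matrix(peaks_to_restraints(NULL), 5),
               matrix(0, 5, 5))
  set.seed(21)
  df <- unique(data.frame(res_i = sample(1:30, 40, TRUE), atom_i = "CA",
                          res_j = sample(1:30, 40, TRUE), atom_j = "CB"))
  r <- restraints_from_pairs(df)
  M <- contact_matrix(r, 30)
  expect_equal(M, t(M))
  s <- summarize_restraints(r, NULL, 30)
  ut <- sum(M[upper.tri(M)])
  expect_equal(ut, s$inter)
  expect_equal(sum(diag(M)), s$intra)
})

test_that("two-state comparison computes CSPs and recovers planted changes", {
  fold <- make_toy_fold(20, "helix-loop-helix", seed = 5)
  pk <- simulate_peaks(fold$structure, labeling_scheme("uniform_13C"),
                       cutoff = 6, seed = 5)$peaks
  same <- compare_states(pk, pk, csp_threshold = 0.1,
                         intensity_threshold = 0.5)
  expect_true(all(same$csp == 0))
  expect_true(all(same$intensity_ratio == 1))
  expect_true(all(same$flag == "unchanged"))
  # 3-4-5 triangle
  a <- peak_row("e", 1, "CA", 2, "CB", s1 = 50, s2 = 30, int = 10)
  b <- peak_row("e", 1, "CA", 2, "CB", s1 = 50.3, s2 = 30.4, int = 10)
  expect_equal(compare_states(a, b, 0.1, 0.5)$csp, 0.5)
  # planted perturbation recovered exactly
  pert <- perturb_state(fold$structure, pk, perturbed_residues = c(3, 7, 15),
                        shift_delta = 0.6, intensity_factor = 0.4, seed = 9)
  cmp <- compare_states(pk, pert$peaks, csp_threshold = 0.3,
                        intensity_threshold = 0.6)
  flagged <- sort(unique(c(cmp$residue[cmp$flag != "unchanged"],
                           pk$res_j[match(which(cmp$flag != "unchanged"),
                                          seq_len(nrow(pk)))])))
  hit <- pk$res_i %in% c(3, 7, 15) | pk$res_j %in% c(3, 7, 15)
  expect_equal(cmp$flag != "unchanged", hit)
  expect_warning(compare_states(a, peak_row("x", 9, "CA", 9, "CB")),
                 "no matchable")
})
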