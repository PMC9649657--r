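# Cross-peak to distance-restraint conversion. Assigned carbon-carbon
# cross-peaks (possibly with up to 5-fold ambiguous candidate assignments)
# become flat-bottom distance restraints with class-dependent bounds; peak
# lists from two sample states can be compared by chemical-shift perturbation
# and intensity ratio.

#' Classify an inter-residue contact by sequence separation
#'
#' Categories follow the standard NMR convention: `intra` (i = j),
#' `sequential` (|i-j| = 1), `medium` (1 < |i-j| < 5), `long` (|i-j| >= 5).
#' The strict form of the medium-range interval (|i-j| in 2..4) is used so
#' sequential and medium are disjoint.
#'
#' @param i,j 1-based residue indices (vectorized)
#' @return character vector of categories
#' @export
classify_contact <- function(i, j) {
  if (any(i < 1) || any(j < 1)) stop("residue indices must be positive")
  d <- abs(i - j)
  ifelse(d == 0, "intra",
         ifelse(d == 1, "sequential",
                ifelse(d < 5, "medium", "long")))
}

#' Distance-restraint bounds by assignment class
#'
#' Intra-residue restraints: 1.5-6.5 A (4.0 +/- 2.5 A); inter-residue
#' restraints: 2.0-7.2 A (4.6 +/- 2.6 A).
#'
#' @param category_class `"intra"` or `"inter"`
#' @return named numeric: `lower`, `upper`, `target`, `tolerance` (Angstrom)
#' @export
assign_bounds <- function(category_class = c("intra", "inter")) {
  category_class <- match.arg(category_class)
  if (category_class == "intra")
    c(lower = 1.5, upper = 6.5, target = 4.0, tolerance = 2.5)
  else
    c(lower = 2.0, upper = 7.2, target = 4.6, tolerance = 2.6)
}

# ---- peak tables ----------------------------------------------------------

PEAK_COLUMNS <- c("exp_id", "res_i", "atom_i", "res_j", "atom_j",
                  "shift1_ppm", "shift2_ppm", "intensity", "alt_assignments")

#' Read a peak table
#'
#' Tab-separated with header columns `exp_id, res_i, atom_i, res_j, atom_j,
#' shift1_ppm, shift2_ppm, intensity, alt_assignments`; `alt_assignments` is a
#' semicolon-separated list of `res.atom-res.atom` tokens naming additional
#' candidate assignments of an ambiguous peak.
#'
#' @param path TSV file path
#' @return data.frame of peaks
#' @export
read_peaks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("exp_id", "res_i", "atom_i", "res_j", "atom_j"),
                     names(df))
  if (length(missing) > 0)
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "))
  for (col in setdiff(PEAK_COLUMNS, names(df))) df[[col]] <- NA
  df$alt_assignments[is.na(df$alt_assignments)] <- ""
  df[, PEAK_COLUMNS]
}

#' Write a peak table
#' @param peaks data.frame of peaks
#' @param path output TSV path
#' @export
write_peaks <- function(peaks, path) {
  write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# candidate assignments of one peak row -> data.frame(res_i, atom_i, res_j, atom_j)
peak_assignments <- function(peak) {
  out <- data.frame(res_i = as.integer(peak$res_i), atom_i = peak$atom_i,
                    res_j = as.integer(peak$res_j), atom_j = peak$atom_j,
                    stringsAsFactors = FALSE)
  alt <- peak$alt_assignments
  if (!is.null(alt) && !is.na(alt) && nzchar(alt)) {
    toks <- strsplit(alt, ";")[[1]]
    for (t in toks) {
      halves <- strsplit(trimws(t), "-")[[1]]
      if (length(halves) != 2) stop("bad alt_assignments token: ", t)
      p1 <- strsplit(halves[1], ".", fixed = TRUE)[[1]]
      p2 <- strsplit(halves[2], ".", fixed = TRUE)[[1]]
      out <- rbind(out, data.frame(res_i = as.integer(p1[1]), atom_i = p1[2],
                                   res_j = as.integer(p2[1]), atom_j = p2[2],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# order-insensitive canonical key of an assignment set
assignment_key <- function(asg) {
  tok <- vapply(seq_len(nrow(asg)), function(m) {
    a <- sprintf("%d.%s", asg$res_i[m], asg$atom_i[m])
    b <- sprintf("%d.%s", asg$res_j[m], asg$atom_j[m])
    paste(sort(c(a, b)), collapse = "-")
  }, "")
  paste(sort(unique(tok)), collapse = ";")
}

new_restraint <- function(assignments, experiments) {
  assignments <- unique(assignments)
  cats <- classify_contact(assignments$res_i, assignments$res_j)
  if (nrow(assignments) == 1) {
    category <- cats[1]
    cls <- if (category == "intra") "intra" else "inter"
  } else {
    category <- "ambiguous"
    # mixed ambiguous sets take the looser inter-residue bounds
    cls <- if (all(cats == "intra")) "intra" else "inter"
  }
  b <- assign_bounds(cls)
  list(assignments = assignments, lower = unname(b["lower"]),
       upper = unname(b["upper"]), target = unname(b["target"]),
       tolerance = unname(b["tolerance"]), category = category,
       experiments = sort(unique(experiments)))
}

#' Convert assigned cross-peaks into distance restraints
#'
#' Each retained peak becomes one restraint with bounds from
#' [assign_bounds()]; peaks whose candidate assignment count exceeds
#' `ambiguity_limit` are dropped (and reported via the `dropped` attribute).
#' Identical assignment sets arising from different experiments are merged by
#' [deduplicate()].
#'
#' @param peaks peak data.frame (see [read_peaks()])
#' @param ambiguity_limit maximum number of candidate assignments (default 5)
#' @return object of class `nmrem_restraints` (a list of restraints)
#' @export
peaks_to_restraints <- function(peaks, ambiguity_limit = 5) {
  res <- list(); dropped <- 0L
  if (!is.null(peaks) && nrow(peaks) > 0) {
    for (p in seq_len(nrow(peaks))) {
      asg <- unique(peak_assignments(peaks[p, ]))
      if (nrow(asg) > ambiguity_limit) { dropped <- dropped + 1L; next }
      res[[length(res) + 1]] <- new_restraint(asg, peaks$exp_id[p])
    }
  }
  out <- structure(res, class = "nmrem_restraints")
  out <- deduplicate(out)
  attr(out, "dropped") <- dropped
  out
}

#' Merge redundant restraints
#'
#' Restraints whose assignment sets are identical (order-insensitive and
#' symmetric in the atom pair) are merged into one, unioning their source
#' experiments. Idempotent.
#'
#' @param restraints an `nmrem_restraints` object
#' @return deduplicated `nmrem_restraints`
#' @export
deduplicate <- function(restraints) {
  if (length(restraints) == 0) return(restraints)
  keys <- vapply(restraints, function(r) assignment_key(r$assignments), "")
  groups <- split(seq_along(restraints), keys)
  # preserve first-appearance order
  groups <- groups[order(vapply(groups, min, 1L))]
  out <- lapply(groups, function(g) {
    r <- restraints[[g[1]]]
    r$experiments <- sort(unique(unlist(lapply(restraints[g],
                                               `[[`, "experiments"))))
    r
  })
  structure(unname(out), class = "nmrem_restraints")
}

#' @export
print.nmrem_restraints <- function(x, ...) {
  cat(sprintf("<%d distance restraints (%d ambiguous)>\n", length(x),
              sum(vapply(x, function(r) r$category == "ambiguous", TRUE))))
  invisible(x)
}

restraint_category <- function(restraints)
  vapply(restraints, `[[`, "", "category")

is_sidechain_atom <- function(a) !(a %in% BACKBONE_ATOMS)

#' Summarize a restraint set
#'
#' @param restraints `nmrem_restraints`
#' @param torsions torsion-restraint data.frame (columns `resi`, `angle`),
#'   or NULL
#' @param n_residues construct length used for the restraints-per-residue
#'   figure
#' @return a `nmrem_restraint_summary` list of counts
#' @export
summarize_restraints <- function(restraints, torsions = NULL,
                                 n_residues = NULL) {
  cats <- restraint_category(restraints)
  counts <- c(intra = sum(cats == "intra"),
              sequential = sum(cats == "sequential"),
              medium = sum(cats == "medium"),
              long = sum(cats == "long"),
              ambiguous = sum(cats == "ambiguous"))
  long_ss <- sum(vapply(restraints, function(r) {
    r$category == "long" &&
      is_sidechain_atom(r$assignments$atom_i[1]) &&
      is_sidechain_atom(r$assignments$atom_j[1])
  }, TRUE))
  inter <- unname(counts["sequential"] + counts["medium"] + counts["long"])
  unamb <- unname(counts["intra"] + inter)
  total <- unamb + unname(counts["ambiguous"])
  phi <- if (is.null(torsions)) 0L else sum(torsions$angle == "phi")
  psi <- if (is.null(torsions)) 0L else sum(torsions$angle == "psi")
  per_res <- NA_real_
  if (!is.null(n_residues)) {
    if (n_residues <= 0) stop("n_residues must be positive")
    per_res <- round(total / n_residues, 2)
  }
  structure(list(
    unambiguous = unamb, intra = unname(counts["intra"]), inter = inter,
    sequential = unname(counts["sequential"]),
    medium = unname(counts["medium"]), long = unname(counts["long"]),
    long_sidechain_sidechain = long_ss,
    ambiguous = unname(counts["ambiguous"]), total = total,
    restraints_per_residue = per_res,
    phi = phi, psi = psi, torsion_total = phi + psi),
    class = "nmrem_restraint_summary")
}

#' @export
print.nmrem_restraint_summary <- function(x, ...) {
  cat("Distance restraints\n")
  cat(sprintf("  Unambiguous            %5d\n", x$unambiguous))
  cat(sprintf("    Intra-residue        %5d\n", x$intra))
  cat(sprintf("    Inter-residue        %5d\n", x$inter))
  cat(sprintf("      Sequential         %5d\n", x$sequential))
  cat(sprintf("      Medium-range       %5d\n", x$medium))
  cat(sprintf("      Long-range (sc-sc) %5d (%d)\n", x$long,
              x$long_sidechain_sidechain))
  cat(sprintf("  Ambiguous              %5d\n", x$ambiguous))
  cat(sprintf("  Total                  %5d\n", x$total))
  if (!is.na(x$restraints_per_residue))
    cat(sprintf("  Restraints/residue     %5.2f\n", x$restraints_per_residue))
  cat(sprintf("Torsion restraints: phi %d, psi %d, total %d\n",
              x$phi, x$psi, x$torsion_total))
  invisible(x)
}

#' Inter-residue contact matrix
#'
#' Symmetric matrix of contact counts; the diagonal holds intra-residue
#' counts. By default only unambiguous restraints contribute; with
#' `ambiguous = TRUE` each candidate pair of an ambiguous restraint adds
#' 1/|assignments|.
#'
#' @param restraints `nmrem_restraints`
#' @param n_residues matrix dimension
#' @param ambiguous include ambiguous restraints fractionally
#' @return `n_residues x n_residues` numeric matrix
#' @export
contact_matrix <- function(restraints, n_residues, ambiguous = FALSE) {
  M <- matrix(0, n_residues, n_residues)
  for (r in restraints) {
    amb <- r$category == "ambiguous"
    if (amb && !ambiguous) next
    w <- if (amb) 1 / nrow(r$assignments) else 1
    for (m in seq_len(nrow(r$assignments))) {
      i <- r$assignments$res_i[m]; j <- r$assignments$res_j[m]
      if (i == j) {
        M[i, i] <- M[i, i] + w
      } else {
        M[i, j] <- M[i, j] + w
        M[j, i] <- M[j, i] + w
      }
    }
  }
  M
}

# ---- torsion restraints ---------------------------------------------------

#' Read a torsion-restraint table
#'
#' TSV with columns `resi`, `angle` (phi/psi), `target_deg`, `tolerance_deg`.
#' A missing tolerance defaults to +/- 20 degrees.
#'
#' @param path TSV path
#' @return data.frame with columns `resi`, `angle`, `target`, `tolerance`
#' @export
read_torsions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- sub("_deg$", "", names(df))
  validate_torsions(df)
}

validate_torsions <- function(df) {
  stopifnot(all(c("resi", "angle", "target") %in% names(df)))
  if (!all(df$angle %in% c("phi", "psi")))
    stop("angle must be 'phi' or 'psi'")
  if (anyDuplicated(df[, c("resi", "angle")]))
    stop("duplicate (residue, angle) torsion restraint")
  if (is.null(df$tolerance)) df$tolerance <- 20
  df$tolerance[is.na(df$tolerance)] <- 20
  if (any(df$tolerance <= 0)) stop("tolerance must be positive")
  if (any(df$target <= -180 | df$target > 180))
    stop("target must lie in (-180, 180]")
  df[, c("resi", "angle", "target", "tolerance")]
}

#' Write a torsion-restraint table
#' @param torsions data.frame (see [read_torsions()])
#' @param path output TSV path
#' @export
write_torsions <- function(torsions, path) {
  out <- data.frame(resi = torsions$resi, angle = torsions$angle,
                    target_deg = torsions$target,
                    tolerance_deg = torsions$tolerance)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- restraint writers ----------------------------------------------------

#' Write restraints as a TSV table
#' @param restraints `nmrem_restraints`
#' @param path output path
#' @export
write_restraints_tsv <- function(restraints, path) {
  rows <- lapply(seq_along(restraints), function(k) {
    r <- restraints[[k]]
    data.frame(id = k, category = r$category,
               n_assign = nrow(r$assignments),
               res_i = r$assignments$res_i[1],
               atom_i = r$assignments$atom_i[1],
               res_j = r$assignments$res_j[1],
               atom_j = r$assignments$atom_j[1],
               lower = r$lower, upper = r$upper, target = r$target,
               tolerance = r$tolerance,
               experiments = paste(r$experiments, collapse = ","),
               alt = if (nrow(r$assignments) > 1)
                 paste(sprintf("%d.%s-%d.%s", r$assignments$res_i[-1],
                               r$assignments$atom_i[-1],
                               r$assignments$res_j[-1],
                               r$assignments$atom_j[-1]), collapse = ";")
               else "")
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write restraints in a generic `assign`-statement text format
#'
#' One line per restraint:
#' `assign (resid I and name X) (resid J and name Y) target dminus dplus`,
#' with `or` continuation lines for ambiguous candidates.
#'
#' @param restraints `nmrem_restraints`
#' @param path output path
#' @export
write_restraints_assign <- function(restraints, path) {
  out <- character(0)
  for (r in restraints) {
    a <- r$assignments
    dminus <- r$target - r$lower
    dplus <- r$upper - r$target
    first <- sprintf(
      "assign (resid %d and name %s) (resid %d and name %s) %.2f %.2f %.2f",
      a$res_i[1], a$atom_i[1], a$res_j[1], a$atom_j[1],
      r$target, dminus, dplus)
    rest <- if (nrow(a) > 1)
      sprintf("    or (resid %d and name %s) (resid %d and name %s)",
              a$res_i[-1], a$atom_i[-1], a$res_j[-1], a$atom_j[-1])
    else character(0)
    out <- c(out, first, rest)
  }
  writeLines(out, path)
  invisible(path)
}

# ---- two-state comparison -------------------------------------------------

#' Compare peak lists from two sample states
#'
#' Matches peaks by (experiment, primary assignment), computes the
#' chemical-shift perturbation (Euclidean distance across the two shift
#' dimensions, with configurable per-dimension weights) and the intensity
#' ratio b/a, and flags each matched peak.
#'
#' @param peaks_a,peaks_b peak data frames of state A (reference) and B
#' @param csp_threshold CSP above which a peak is flagged `shifted` (ppm)
#' @param intensity_threshold ratio below which a peak is flagged `attenuated`
#' @param weights length-2 weights of the two shift dimensions (both 1 for a
#'   homonuclear carbon-carbon peak)
#' @return data.frame with `residue`, `csp`, `intensity_ratio`, `flag`;
#'   unmatched peaks are reported in attributes `unmatched_a`/`unmatched_b`
#' @export
compare_states <- function(peaks_a, peaks_b, csp_threshold = 0.2,
                           intensity_threshold = 0.5, weights = c(1, 1)) {
  key <- function(p) paste(p$exp_id, p$res_i, p$atom_i, p$res_j, p$atom_j)
  ka <- key(peaks_a); kb <- key(peaks_b)
  ia <- match(kb, ka)
  matched_b <- which(!is.na(ia))
  if (length(matched_b) == 0) {
    warning("no matchable peaks between the two states")
    out <- data.frame(residue = integer(0), csp = numeric(0),
                      intensity_ratio = numeric(0), flag = character(0))
    return(out)
  }
  a <- peaks_a[ia[matched_b], ]; b <- peaks_b[matched_b, ]
  d1 <- (b$shift1_ppm - a$shift1_ppm) * weights[1]
  d2 <- (b$shift2_ppm - a$shift2_ppm) * weights[2]
  csp <- sqrt(d1^2 + d2^2)
  ratio <- b$intensity / a$intensity
  flag <- ifelse(csp >= csp_threshold, "shifted",
                 ifelse(ratio <= intensity_threshold, "attenuated",
                        "unchanged"))
  out <- data.frame(residue = a$res_i, csp = csp, intensity_ratio = ratio,
                    flag = flag, stringsAsFactors = FALSE)
  attr(out, "unmatched_a") <- peaks_a[setdiff(seq_len(nrow(peaks_a)),
                                              ia[matched_b]), ]
  attr(out, "unmatched_b") <- peaks_b[is.na(ia), ]
  out
}
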