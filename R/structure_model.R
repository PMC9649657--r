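# Structure representation: ordered heavy atoms with residue/chain topology and
# ideal covalent geometry (Engh/Huber-style parameters). Hydrogens are omitted
# throughout: the restraints driving refinement are carbon-carbon distances and
# backbone density terms, so protons add cost without testable benefit.

# ideal covalent geometry (lengths in Angstrom, angles/torsions in degrees)
GEOM <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  b_CA_CB = 1.530, b_CB_CG = 1.520, b_CG_CD = 1.520,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7,
  a_CA_C_O = 120.8, a_C_CA_CB = 110.1, a_CA_CB_CG = 114.0, a_CB_CG_CD = 114.0,
  imp_omega = 180, imp_O = 180, imp_CB = 122.6
)

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- setNames(names(AA3), AA3)

# pseudo-sidechain carbon count per residue type (CB, CG, CD); enough to
# exercise sidechain-sidechain restraints without rotamer machinery
SIDE_N <- c(G = 0L, A = 1L, S = 1L, C = 1L, D = 2L, N = 2L, T = 2L, V = 2L,
            P = 2L, E = 3L, Q = 3L, H = 2L, I = 3L, L = 3L, K = 3L, M = 3L,
            F = 2L, R = 3L, W = 2L, Y = 2L)
SIDE_NAMES <- c("CB", "CG", "CD")

ELEMENT_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008,
                  P = 30.974)

element_mass <- function(elem) {
  m <- ELEMENT_MASS[elem]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Construct a Structure object
#'
#' @param atoms data.frame with columns `chain`, `resi` (1-based integer,
#'   strictly increasing within a chain), `resn` (3-letter), `atom`, `elem`,
#'   `x`, `y`, `z`
#' @param sequence optional one-letter sequence; derived from `atoms` if NULL
#' @param topology optional list of `bonds`, `angles`, `impropers` data frames
#'   carrying 1-based atom indices and ideal values; built from standard
#'   parameters if NULL
#' @return an object of class `nmrem_structure`
#' @export
new_structure <- function(atoms, sequence = NULL, topology = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resi", "resn", "atom", "elem", "x", "y", "z")
                %in% names(atoms)))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resi[atoms$chain == ch]
    if (any(diff(unique(r)) <= 0) || any(diff(r) < 0))
      stop("residue indices must be non-decreasing within a chain")
  }
  rownames(atoms) <- NULL
  if (is.null(sequence)) {
    res <- atoms[!duplicated(atoms[, c("chain", "resi")]), ]
    lett <- AA1[res$resn]
    lett[is.na(lett)] <- "X"
    sequence <- paste(lett, collapse = "")
  }
  s <- structure(list(atoms = atoms, sequence = sequence, topology = topology),
                 class = "nmrem_structure")
  if (is.null(topology))
    s$topology <- tryCatch(build_topology(atoms), error = function(e) NULL)
  s
}

#' @export
print.nmrem_structure <- function(x, ...) {
  cat(sprintf("<structure: %d atoms, %d residues, chain(s) %s>\n",
              nrow(x$atoms), n_residues(x),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix
#' @param x a structure
#' @return numeric matrix (Angstrom)
#' @export
coords <- function(x) UseMethod("coords")

#' @export
coords.nmrem_structure <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param x a structure
#' @param value n x 3 numeric matrix
#' @export
`coords<-` <- function(x, value) {
  stopifnot(nrow(value) == nrow(x$atoms), ncol(value) == 3)
  x$atoms$x <- value[, 1]; x$atoms$y <- value[, 2]; x$atoms$z <- value[, 3]
  x
}

#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @export
n_residues <- function(x) nrow(unique(x$atoms[, c("chain", "resi")]))

atom_masses <- function(x) element_mass(x$atoms$elem)

# 1-based atom index for (resi, atom name); 0 when absent
atom_lookup <- function(atoms, resi, name) {
  key <- paste(atoms$resi, atoms$atom)
  match(paste(resi, name), key, nomatch = 0L)
}

# ---- ideal topology -------------------------------------------------------

# Build bonds/angles/impropers with ideal values from the standard parameter
# table, assuming the package's reduced heavy-atom naming (N, CA, C, O + up to
# CB/CG/CD pseudo-sidechain carbons) and a single chain per chain id.
build_topology <- function(atoms) {
  bonds <- list(); angles <- list(); imps <- list()
  g <- GEOM
  idx <- function(resi, name, ch) {
    sub <- which(atoms$chain == ch & atoms$resi == resi & atoms$atom == name)
    if (length(sub) == 0) 0L else sub[1]
  }
  for (ch in unique(atoms$chain)) {
    resis <- sort(unique(atoms$resi[atoms$chain == ch]))
    for (ri in seq_along(resis)) {
      r <- resis[ri]
      iN <- idx(r, "N", ch); iCA <- idx(r, "CA", ch); iC <- idx(r, "C", ch)
      iO <- idx(r, "O", ch); iCB <- idx(r, "CB", ch); iCG <- idx(r, "CG", ch)
      iCD <- idx(r, "CD", ch)
      if (iN && iCA) bonds[[length(bonds)+1]] <- c(iN, iCA, g$b_N_CA)
      if (iCA && iC) bonds[[length(bonds)+1]] <- c(iCA, iC, g$b_CA_C)
      if (iC && iO)  bonds[[length(bonds)+1]] <- c(iC, iO, g$b_C_O)
      if (iCA && iCB) bonds[[length(bonds)+1]] <- c(iCA, iCB, g$b_CA_CB)
      if (iCB && iCG) bonds[[length(bonds)+1]] <- c(iCB, iCG, g$b_CB_CG)
      if (iCG && iCD) bonds[[length(bonds)+1]] <- c(iCG, iCD, g$b_CG_CD)
      if (iN && iCA && iC)
        angles[[length(angles)+1]] <- c(iN, iCA, iC, g$a_N_CA_C)
      if (iCA && iC && iO)
        angles[[length(angles)+1]] <- c(iCA, iC, iO, g$a_CA_C_O)
      if (iC && iCA && iCB)
        angles[[length(angles)+1]] <- c(iC, iCA, iCB, g$a_C_CA_CB)
      if (iCA && iCB && iCG)
        angles[[length(angles)+1]] <- c(iCA, iCB, iCG, g$a_CA_CB_CG)
      if (iCB && iCG && iCD)
        angles[[length(angles)+1]] <- c(iCB, iCG, iCD, g$a_CB_CG_CD)
      if (iN && iC && iCA && iCB)
        imps[[length(imps)+1]] <- c(iN, iC, iCA, iCB, g$imp_CB)
      if (ri < length(resis) && resis[ri + 1] == r + 1) {
        iN2 <- idx(r + 1, "N", ch); iCA2 <- idx(r + 1, "CA", ch)
        if (iC && iN2) bonds[[length(bonds)+1]] <- c(iC, iN2, g$b_C_N)
        if (iCA && iC && iN2)
          angles[[length(angles)+1]] <- c(iCA, iC, iN2, g$a_CA_C_N)
        if (iC && iN2 && iCA2)
          angles[[length(angles)+1]] <- c(iC, iN2, iCA2, g$a_C_N_CA)
        if (iCA && iC && iN2 && iCA2)
          imps[[length(imps)+1]] <- c(iCA, iC, iN2, iCA2, g$imp_omega)
        if (iN2 && iCA && iC && iO)
          imps[[length(imps)+1]] <- c(iN2, iCA, iC, iO, g$imp_O)
      }
    }
  }
  as_df <- function(lst, nm) {
    if (length(lst) == 0)
      return(setNames(as.data.frame(matrix(numeric(0), 0, length(nm))), nm))
    setNames(as.data.frame(do.call(rbind, lst)), nm)
  }
  b <- as_df(bonds, c("i", "j", "r0"))
  a <- as_df(angles, c("i", "j", "k", "th0"))
  im <- as_df(imps, c("i", "j", "k", "l", "phi0"))
  for (col in c("i", "j")) b[[col]] <- as.integer(b[[col]])
  for (col in c("i", "j", "k")) a[[col]] <- as.integer(a[[col]])
  for (col in c("i", "j", "k", "l")) im[[col]] <- as.integer(im[[col]])
  list(bonds = b, angles = a, impropers = im)
}

# ---- chain construction ---------------------------------------------------

# Build an ideal-geometry chain from per-residue (phi, psi) torsions.
# Returns the atoms data.frame; all bonds/angles/impropers are exactly at the
# ideal values of GEOM, so geometry_deviations() is identically zero.
build_chain_atoms <- function(sequence, phi, psi, chain = "A", chi1 = -60,
                              chi2 = 180, start_resi = 1L) {
  n <- nchar(sequence)
  stopifnot(length(phi) == n, length(psi) == n)
  lett <- strsplit(sequence, "")[[1]]
  g <- GEOM
  out <- list()
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_N_CA, 0, 0)
  th <- deg2rad(g$a_N_CA_C)
  C[1, ] <- CA[1, ] + g$b_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i-1, ], CA[i-1, ], C[i-1, ],
                           g$b_C_N, g$a_CA_C_N, psi[i-1])
      CA[i, ] <- nerf_place(CA[i-1, ], C[i-1, ], N[i, ],
                            g$b_N_CA, g$a_C_N_CA, g$imp_omega)
      C[i, ] <- nerf_place(C[i-1, ], N[i, ], CA[i, ],
                           g$b_CA_C, g$a_N_CA_C, phi[i])
    }
  }
  for (i in seq_len(n)) {
    resn <- AA3[lett[i]]
    if (is.na(resn)) stop("unknown residue letter: ", lett[i])
    resi <- start_resi + i - 1L
    add <- function(name, elem, p)
      out[[length(out)+1]] <<- data.frame(chain = chain, resi = resi,
                                          resn = resn, atom = name,
                                          elem = elem, x = p[1], y = p[2],
                                          z = p[3], stringsAsFactors = FALSE)
    add("N", "N", N[i, ]); add("CA", "C", CA[i, ]); add("C", "C", C[i, ])
    if (i < n) {
      Nn <- nerf_place(N[i, ], CA[i, ], C[i, ], g$b_C_N, g$a_CA_C_N, psi[i])
      O <- nerf_place(Nn, CA[i, ], C[i, ], g$b_C_O, g$a_CA_C_O, g$imp_O)
    } else {
      O <- nerf_place(N[i, ], CA[i, ], C[i, ], g$b_C_O, g$a_CA_C_O,
                      psi[i] + 180)
    }
    add("O", "O", O)
    ns <- SIDE_N[lett[i]]
    if (ns >= 1) {
      CB <- nerf_place(N[i, ], C[i, ], CA[i, ], g$b_CA_CB, g$a_C_CA_CB,
                       g$imp_CB)
      add("CB", "C", CB)
      if (ns >= 2) {
        CG <- nerf_place(N[i, ], CA[i, ], CB, g$b_CB_CG, g$a_CA_CB_CG, chi1)
        add("CG", "C", CG)
        if (ns >= 3) {
          CD <- nerf_place(CA[i, ], CB, CG, g$b_CG_CD, g$a_CB_CG_CD, chi2)
          add("CD", "C", CD)
        }
      }
    }
  }
  do.call(rbind, out)
}

# phi/psi of a chain measured from coordinates; NA at chain ends
measure_torsions <- function(s) {
  at <- s$atoms
  resis <- sort(unique(at$resi))
  X <- coords(s)
  get <- function(r, nm) {
    i <- which(at$resi == r & at$atom == nm)
    if (length(i) == 0) NULL else X[i[1], ]
  }
  phi <- psi <- rep(NA_real_, length(resis))
  for (k in seq_along(resis)) {
    r <- resis[k]
    Np <- get(r, "N"); CAp <- get(r, "CA"); Cp <- get(r, "C")
    Cm <- get(r - 1, "C"); Nn <- get(r + 1, "N")
    if (!is.null(Cm) && !is.null(Np) && !is.null(CAp) && !is.null(Cp))
      phi[k] <- dihedral(Cm, Np, CAp, Cp)
    if (!is.null(Np) && !is.null(CAp) && !is.null(Cp) && !is.null(Nn))
      psi[k] <- dihedral(Np, CAp, Cp, Nn)
  }
  data.frame(resi = resis, phi = phi, psi = psi)
}

# ---- selections -----------------------------------------------------------

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Select atoms with a small selection language
#'
#' Supported tokens, combined conjunctively: `backbone` (N, CA, C, O),
#' `heavy` (all atoms), `name CA` (comma-separated names), and
#' `resi 321-349` (comma-separated indices or ranges).
#'
#' @param x a structure
#' @param selection selection string
#' @return integer vector of 1-based atom indices
#' @export
select_atoms <- function(x, selection = "heavy") {
  at <- x$atoms
  keep <- rep(TRUE, nrow(at))
  toks <- strsplit(trimws(selection), "\\s+")[[1]]
  toks <- toks[toks != "and"]
  i <- 1
  while (i <= length(toks)) {
    t <- tolower(toks[i])
    if (t == "backbone") {
      keep <- keep & at$atom %in% BACKBONE_ATOMS
    } else if (t == "heavy") {
      keep <- keep & at$elem != "H"
    } else if (t == "name") {
      i <- i + 1
      if (i > length(toks)) stop("selection: 'name' needs an argument")
      nm <- strsplit(toks[i], ",")[[1]]
      keep <- keep & at$atom %in% nm
    } else if (t == "resi") {
      i <- i + 1
      if (i > length(toks)) stop("selection: 'resi' needs an argument")
      parts <- strsplit(toks[i], ",")[[1]]
      rr <- integer(0)
      for (p in parts) {
        if (grepl("-", p)) {
          ab <- as.integer(strsplit(p, "-")[[1]])
          rr <- c(rr, seq(ab[1], ab[2]))
        } else rr <- c(rr, as.integer(p))
      }
      keep <- keep & at$resi %in% rr
    } else {
      stop("selection: unknown token '", toks[i], "'")
    }
    i <- i + 1
  }
  which(keep)
}

# ---- coordinate file I/O --------------------------------------------------

infer_element <- function(name) {
  first <- sub("^[0-9']*", "", name)
  e <- toupper(substr(first, 1, 1))
  ifelse(e %in% names(ELEMENT_MASS), e, "C")
}

parse_pdb_lines <- function(lines, offset = 0) {
  recs <- grepl("^(ATOM|HETATM)", lines)
  ln <- which(recs)
  if (length(ln) == 0) stop("no ATOM records found")
  f <- lines[ln]
  num <- function(s, from, to) {
    v <- suppressWarnings(as.numeric(trimws(substr(s, from, to))))
    if (any(is.na(v))) {
      bad <- ln[which(is.na(v))[1]] + offset
      stop("malformed PDB record at line ", bad)
    }
    v
  }
  atom <- trimws(substr(f, 13, 16))
  resn <- trimws(substr(f, 18, 20))
  chain <- trimws(substr(f, 22, 22))
  chain[chain == ""] <- "A"
  resi <- as.integer(num(f, 23, 26))
  x <- num(f, 31, 38); y <- num(f, 39, 46); z <- num(f, 47, 54)
  elem <- trimws(substr(f, 77, 78))
  miss <- elem == "" | is.na(elem)
  elem[miss] <- infer_element(atom[miss])
  df <- data.frame(chain = chain, resi = resi, resn = resn, atom = atom,
                   elem = elem, x = x, y = y, z = z, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(df$resn), names(AA1))
  if (length(unknown) > 0)
    warning("unknown residue name(s) kept as-is: ",
            paste(unknown, collapse = ", "))
  df
}

#' Read a coordinate file
#'
#' Reads PDB or mmCIF. A multi-MODEL PDB returns a list of structures (an
#' ensemble); otherwise a single structure.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`
#' @return `nmrem_structure` or a list of them (class `nmrem_ensemble`)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  if (format == "cif") return(read_cif(path))
  lines <- readLines(path, warn = FALSE)
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 1) {
    mend <- grep("^ENDMDL", lines)
    if (length(mend) < length(mstart)) mend <- c(mend, length(lines))
    ens <- lapply(seq_along(mstart), function(m) {
      seg <- lines[mstart[m]:mend[m]]
      new_structure(parse_pdb_lines(seg, offset = mstart[m] - 1))
    })
    class(ens) <- "nmrem_ensemble"
    return(ens)
  }
  new_structure(parse_pdb_lines(lines))
}

format_pdb_atoms <- function(at, serial_start = 1L) {
  name4 <- ifelse(nchar(at$atom) < 4, sprintf(" %-3s", at$atom),
                  sprintf("%-4s", at$atom))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
          seq_len(nrow(at)) + serial_start - 1L, name4, at$resn,
          substr(at$chain, 1, 1), at$resi, at$x, at$y, at$z, 1, 0,
          substr(at$chain, 1, 4), at$elem)
}

#' Write a coordinate file
#'
#' @param x a structure, an ensemble (list of structures; written as
#'   MODEL/ENDMDL blocks), or an assembly (subunits written under their
#'   segment ids)
#' @param path output path
#' @param format `"auto"`, `"pdb"`, or `"cif"`
#' @export
write_structure <- function(x, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  if (format == "cif") return(write_cif(x, path))
  if (inherits(x, "nmrem_assembly")) {
    at <- do.call(rbind, lapply(seq_along(x$subunits), function(i) {
      a <- x$subunits[[i]]$atoms
      a$chain <- x$segment_ids[i]
      a
    }))
    writeLines(c(format_pdb_atoms(at), "END"), path)
    return(invisible(path))
  }
  if (inherits(x, "nmrem_ensemble") ||
      (is.list(x) && !inherits(x, "nmrem_structure") &&
       all(vapply(x, inherits, TRUE, "nmrem_structure")))) {
    out <- character(0)
    for (m in seq_along(x)) {
      out <- c(out, sprintf("MODEL %8d", m),
               format_pdb_atoms(x[[m]]$atoms), "ENDMDL")
    }
    writeLines(c(out, "END"), path)
    return(invisible(path))
  }
  writeLines(c(format_pdb_atoms(x$atoms), "END"), path)
  invisible(path)
}

read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^_atom_site\\.", lines)
  if (length(hdr) == 0) stop("no _atom_site loop found in mmCIF file")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr]))
  body <- lines[(max(hdr) + 1):length(lines)]
  stop_at <- grep("^(#|loop_|_)", body)
  if (length(stop_at) > 0) body <- body[seq_len(stop_at[1] - 1)]
  body <- body[trimws(body) != ""]
  toks <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(toks, length, 1L) != length(fields))
  if (length(bad) > 0)
    stop("malformed mmCIF atom_site row at line ", max(hdr) + bad[1])
  tab <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  names(tab) <- fields
  df <- data.frame(
    chain = tab[["auth_asym_id"]] %||% tab[["label_asym_id"]],
    resi = as.integer(tab[["auth_seq_id"]] %||% tab[["label_seq_id"]]),
    resn = tab[["label_comp_id"]],
    atom = tab[["label_atom_id"]],
    elem = tab[["type_symbol"]] %||% infer_element(tab[["label_atom_id"]]),
    x = as.numeric(tab[["Cartn_x"]]), y = as.numeric(tab[["Cartn_y"]]),
    z = as.numeric(tab[["Cartn_z"]]), stringsAsFactors = FALSE)
  new_structure(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_cif <- function(x, path) {
  if (inherits(x, "nmrem_assembly")) x <- assembly_to_structure(x)
  at <- x$atoms
  hdr <- c("data_nmrem", "#", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_comp_id",
                                   "auth_asym_id", "auth_seq_id",
                                   "Cartn_x", "Cartn_y", "Cartn_z")))
  rows <- sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f",
                  seq_len(nrow(at)), at$elem, at$atom, at$resn, at$chain,
                  at$resi, at$x, at$y, at$z)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

# ---- superposition and ensemble statistics --------------------------------

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares fit of the selected atoms of `mobile` onto `reference`.
#' The returned transform maps mobile coordinates as
#' `x %*% t(rotation) + translation`.
#'
#' @param reference,mobile structures with matching selections
#' @param selection selection string (see [select_atoms()])
#' @return list with `rotation` (proper 3x3), `translation`, `rmsd` and
#'   `transformed` (the full mobile structure after the fit)
#' @export
superpose <- function(reference, mobile, selection = "heavy") {
  ir <- select_atoms(reference, selection)
  im <- select_atoms(mobile, selection)
  if (length(ir) != length(im))
    stop("selection maps to different atom counts (", length(ir), " vs ",
         length(im), ")")
  fit <- kabsch_fit(coords(reference)[ir, , drop = FALSE],
                    coords(mobile)[im, , drop = FALSE])
  out <- mobile
  coords(out) <- apply_transform(coords(mobile), fit$rotation, fit$translation)
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, transformed = out),
            class = "nmrem_superposition")
}

#' @export
print.nmrem_superposition <- function(x, ...) {
  cat(sprintf("<superposition: rmsd %.4f A>\n", x$rmsd))
  invisible(x)
}

check_matching_atoms <- function(ensemble) {
  ref <- ensemble[[1]]$atoms
  for (m in seq_along(ensemble)[-1]) {
    a <- ensemble[[m]]$atoms
    if (nrow(a) != nrow(ref))
      stop("member ", m, " has ", nrow(a), " atoms, expected ", nrow(ref))
    bad <- which(a$atom != ref$atom | a$resi != ref$resi)
    if (length(bad) > 0)
      stop("member ", m, " atom mismatch at position ", bad[1], ": ",
           a$resi[bad[1]], " ", a$atom[bad[1]], " vs ", ref$resi[bad[1]],
           " ", ref$atom[bad[1]])
  }
  invisible(TRUE)
}

#' Pairwise ensemble RMSD
#'
#' Superposes every unordered pair of ensemble members on the given selection
#' and reports the mean and standard deviation of the pairwise RMSDs, plus the
#' full matrix.
#'
#' @param ensemble list of structures with identical atom ordering
#' @param selection `"backbone"` (N, CA, C) or any selection string
#' @return list with `mean`, `sd`, `matrix`
#' @export
pairwise_ensemble_rmsd <- function(ensemble, selection = "backbone") {
  if (inherits(ensemble, "nmrem_assembly")) ensemble <- ensemble$subunits
  if (length(ensemble) < 2) stop("need at least 2 ensemble members")
  check_matching_atoms(ensemble)
  # conventional NMR backbone statistic uses N, CA, C'
  if (identical(selection, "backbone")) selection <- "name N,CA,C"
  n <- length(ensemble)
  M <- matrix(0, n, n)
  vals <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- superpose(ensemble[[i]], ensemble[[j]], selection)$rmsd
    M[i, j] <- M[j, i] <- r
    vals <- c(vals, r)
  }
  list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
       matrix = M)
}

#' Deviations from idealized covalent geometry
#'
#' Root-mean-square deviation of bond lengths, bond angles and improper
#' angles from their ideal values in the structure's topology.
#'
#' @param x a structure (topology must be populated)
#' @return named numeric: `bond` (Angstrom), `angle` (degrees),
#'   `improper` (degrees)
#' @export
geometry_deviations <- function(x) {
  top <- x$topology
  if (is.null(top) || (nrow(top$bonds) == 0 && nrow(top$angles) == 0))
    stop("structure has no topology")
  X <- coords(x)
  bd <- if (nrow(top$bonds) > 0) {
    obs <- sqrt(rowSums((X[top$bonds$i, , drop = FALSE] -
                         X[top$bonds$j, , drop = FALSE])^2))
    sqrt(mean((obs - top$bonds$r0)^2))
  } else 0
  ad <- if (nrow(top$angles) > 0) {
    obs <- vapply(seq_len(nrow(top$angles)), function(m)
      bond_angle(X[top$angles$i[m], ], X[top$angles$j[m], ],
                 X[top$angles$k[m], ]), 0)
    sqrt(mean((obs - top$angles$th0)^2))
  } else 0
  id <- if (nrow(top$impropers) > 0) {
    obs <- vapply(seq_len(nrow(top$impropers)), function(m)
      dihedral(X[top$impropers$i[m], ], X[top$impropers$j[m], ],
               X[top$impropers$k[m], ], X[top$impropers$l[m], ]), 0)
    sqrt(mean(wrap_angle(obs - top$impropers$phi0)^2))
  } else 0
  c(bond = bd, angle = ad, improper = id)
}

# ---- chain extension ------------------------------------------------------

#' Extend a chain with missing residues
#'
#' Appends residues of `full_sequence` absent from the structure in an
#' extended conformation with ideal covalent geometry. Terminal extensions are
#' built outward by internal-coordinate placement; internal gaps are closed by
#' a short covalent-geometry minimization of the added atoms only.
#'
#' @param x a single-chain structure
#' @param full_sequence one-letter target sequence (position = residue index)
#' @return structure with one residue per sequence position
#' @export
extend_chain <- function(x, full_sequence) {
  at <- x$atoms
  ch <- at$chain[1]
  nfull <- nchar(full_sequence)
  lett <- strsplit(full_sequence, "")[[1]]
  have <- sort(unique(at$resi))
  if (max(have) > nfull) stop("structure has residues beyond full_sequence")
  seq_have <- strsplit(x$sequence, "")[[1]]
  for (k in seq_along(have)) {
    if (seq_have[k] != "X" && seq_have[k] != lett[have[k]])
      stop("sequence mismatch at position ", have[k], ": structure has ",
           seq_have[k], ", full_sequence has ", lett[have[k]])
  }
  missing <- setdiff(seq_len(nfull), have)
  if (length(missing) == 0) return(x)

  ext_phi <- -120; ext_psi <- 120 # extended-strand torsions for new residues
  getp <- function(a, r, nm) {
    i <- which(a$resi == r & a$atom == nm)
    if (length(i) == 0) NULL else as.numeric(a[i[1], c("x", "y", "z")])
  }
  runs <- split(missing, cumsum(c(1, diff(missing) != 1)))
  had_internal <- FALSE
  for (run in runs) {
    r0 <- min(run); r1 <- max(run)
    if (r0 - 1 %in% at$resi) {
      # forward build from the residue before the gap
      for (r in r0:r1) {
        g <- GEOM
        Np <- getp(at, r - 1, "N"); CAp <- getp(at, r - 1, "CA")
        Cp <- getp(at, r - 1, "C")
        N <- nerf_place(Np, CAp, Cp, g$b_C_N, g$a_CA_C_N, ext_psi)
        CA <- nerf_place(CAp, Cp, N, g$b_N_CA, g$a_C_N_CA, g$imp_omega)
        C <- nerf_place(Cp, N, CA, g$b_CA_C, g$a_N_CA_C, ext_phi)
        at <- append_residue(at, ch, r, lett[r], N, CA, C, ext_psi)
        if ((r - 1) %in% run) {
          # re-place the previously added residue's O against the new N so the
          # carbonyl-planarity improper is exactly ideal
          io <- which(at$resi == r - 1 & at$atom == "O")
          O <- nerf_place(N, CAp, Cp, g$b_C_O, g$a_CA_C_O, g$imp_O)
          at[io, c("x", "y", "z")] <- as.list(O)
        }
      }
      if (r1 + 1 %in% have) had_internal <- TRUE
    } else if (r1 + 1 %in% at$resi) {
      # backward build toward the N terminus
      for (r in r1:r0) {
        g <- GEOM
        Nn <- getp(at, r + 1, "N"); CAn <- getp(at, r + 1, "CA")
        Cn <- getp(at, r + 1, "C")
        C <- nerf_place(Cn, CAn, Nn, g$b_C_N, g$a_C_N_CA, ext_phi)
        CA <- nerf_place(CAn, Nn, C, g$b_CA_C, g$a_CA_C_N, g$imp_omega)
        N <- nerf_place(Nn, C, CA, g$b_N_CA, g$a_N_CA_C, ext_psi)
        at <- append_residue(at, ch, r, lett[r], N, CA, C, ext_psi)
        io <- which(at$resi == r & at$atom == "O")
        O <- nerf_place(Nn, CA, C, g$b_C_O, g$a_CA_C_O, g$imp_O)
        at[io, c("x", "y", "z")] <- as.list(O)
      }
    } else stop("gap not anchored to any existing residue")
  }
  ord <- order(at$resi, match(at$atom, c("N", "CA", "C", "O", SIDE_NAMES)))
  at <- at[ord, ]
  out <- new_structure(at, sequence = full_sequence)
  added_idx <- which(out$atoms$resi %in% missing)
  clash <- min_cross_distance(coords(out), added_idx, out$atoms$resi) < 1.5
  if (had_internal || clash) {
    sys <- make_system(out, config = energy_config(k_repel = 10, r_repel = 2.2))
    out <- minimize(sys, free = added_idx, max_iter = 500)$structure
  }
  out
}

append_residue <- function(at, ch, resi, lett, N, CA, C, psi) {
  g <- GEOM
  resn <- AA3[lett]
  rows <- list(
    data.frame(chain = ch, resi = resi, resn = resn, atom = "N", elem = "N",
               x = N[1], y = N[2], z = N[3], stringsAsFactors = FALSE),
    data.frame(chain = ch, resi = resi, resn = resn, atom = "CA", elem = "C",
               x = CA[1], y = CA[2], z = CA[3], stringsAsFactors = FALSE),
    data.frame(chain = ch, resi = resi, resn = resn, atom = "C", elem = "C",
               x = C[1], y = C[2], z = C[3], stringsAsFactors = FALSE))
  O <- nerf_place(N, CA, C, g$b_C_O, g$a_CA_C_O, psi + 180)
  rows[[4]] <- data.frame(chain = ch, resi = resi, resn = resn, atom = "O",
                          elem = "O", x = O[1], y = O[2], z = O[3],
                          stringsAsFactors = FALSE)
  ns <- SIDE_N[lett]
  if (ns >= 1) {
    CB <- nerf_place(N, C, CA, g$b_CA_CB, g$a_C_CA_CB, g$imp_CB)
    rows[[length(rows)+1]] <- data.frame(chain = ch, resi = resi, resn = resn,
                                         atom = "CB", elem = "C", x = CB[1],
                                         y = CB[2], z = CB[3],
                                         stringsAsFactors = FALSE)
    if (ns >= 2) {
      CG <- nerf_place(N, CA, CB, g$b_CB_CG, g$a_CA_CB_CG, -60)
      rows[[length(rows)+1]] <- data.frame(chain = ch, resi = resi,
                                           resn = resn, atom = "CG",
                                           elem = "C", x = CG[1], y = CG[2],
                                           z = CG[3], stringsAsFactors = FALSE)
      if (ns >= 3) {
        CD <- nerf_place(CA, CB, CG, g$b_CG_CD, g$a_CB_CG_CD, 180)
        rows[[length(rows)+1]] <- data.frame(chain = ch, resi = resi,
                                             resn = resn, atom = "CD",
                                             elem = "C", x = CD[1], y = CD[2],
                                             z = CD[3],
                                             stringsAsFactors = FALSE)
      }
    }
  }
  rbind(at, do.call(rbind, rows))
}

# minimum distance between the atoms in idx and all other atoms at least two
# residues away (adjacent residues are covalently linked)
min_cross_distance <- function(X, idx, resi) {
  other <- setdiff(seq_len(nrow(X)), idx)
  if (length(other) == 0 || length(idx) == 0) return(Inf)
  dmin <- Inf
  for (i in idx) {
    far <- other[abs(resi[other] - resi[i]) >= 2]
    if (length(far) == 0) next
    d2 <- rowSums(sweep(X[far, , drop = FALSE], 2, X[i, ])^2)
    dmin <- min(dmin, sqrt(min(d2)))
  }
  dmin
}

# ---- assemblies -----------------------------------------------------------

#' Replicate a structure into a multi-subunit assembly
#'
#' @param x template structure
#' @param n number of subunits
#' @param segment_ids unique single-character labels (default A, B, ...)
#' @return object of class `nmrem_assembly` with independent deep-copied
#'   subunits sharing one topology template
#' @export
replicate_subunits <- function(x, n, segment_ids = NULL) {
  stopifnot(n >= 1)
  if (is.null(segment_ids))
    segment_ids <- c(LETTERS, letters)[seq_len(n)]
  if (length(segment_ids) != n) stop("need ", n, " segment ids")
  if (anyDuplicated(segment_ids)) stop("duplicate segment ids")
  subs <- lapply(seq_len(n), function(i) {
    s <- x
    s$atoms$chain <- segment_ids[i]
    s
  })
  structure(list(subunits = subs, segment_ids = segment_ids,
                 template = x), class = "nmrem_assembly")
}

#' @export
print.nmrem_assembly <- function(x, ...) {
  cat(sprintf("<assembly: %d subunits (%s), %d atoms each>\n",
              length(x$subunits), paste(x$segment_ids, collapse = ""),
              nrow(x$subunits[[1]]$atoms)))
  invisible(x)
}

# flatten an assembly into one structure (chains = segment ids)
assembly_to_structure <- function(a) {
  at <- do.call(rbind, lapply(seq_along(a$subunits), function(i) {
    d <- a$subunits[[i]]$atoms
    d$chain <- a$segment_ids[i]
    d
  }))
  new_structure(at, topology = NULL)
}
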