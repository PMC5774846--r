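#' @useDynLib topomol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dist rnorm runif sd setNames
#' @importFrom utils read.table write.table head combn
NULL

# Covalent and van der Waals radii (Angstrom) for the elements handled by the
# featurization recipes; unknown symbols fall back to generic values so that
# exotic atoms (metals etc.) still parse.
.covalent_radius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                      P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39)
.vdw_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)

covalent_radius <- function(element) {
  r <- .covalent_radius[element]
  r[is.na(r)] <- 1.5
  unname(r)
}

vdw_radius <- function(element) {
  r <- .vdw_radius[element]
  r[is.na(r)] <- 2.0
  unname(r)
}

#' Construct a molecule
#'
#' A `Molecule` is an ordered set of atoms (element symbol, 3-D coordinates in
#' Angstrom, optional partial charge, protein/ligand role) plus an undirected
#' covalent bond list over atom indices.
#'
#' @param atoms data frame with columns `serial`, `element`, `x`, `y`, `z`,
#'   and optionally `charge` (elementary-charge units) and `role`
#'   (`"protein"` or `"ligand"`).
#' @param bonds two-column integer matrix of atom index pairs (1-based); may
#'   have zero rows.
#' @param id free-text label.
#' @return an object of class `Molecule`.
#' @export
molecule <- function(atoms, bonds = matrix(integer(), ncol = 2), id = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("element", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns element, x, y, z")
  n <- nrow(atoms)
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(n)
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"role" %in% names(atoms)) atoms$role <- "ligand"
  if (n > 0 && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L) || any(bonds > n))
      stop("bond indices out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
    bonds <- t(apply(bonds, 1, sort))           # canonical undirected form
    bonds <- unique(bonds)
    bonds <- matrix(as.integer(bonds), ncol = 2)
  }
  structure(list(atoms = atoms, bonds = bonds, id = id), class = "Molecule")
}

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf("<Molecule '%s': %d atoms, %d bonds>\n",
              x$id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

#' Construct a protein-ligand complex
#'
#' Wraps a protein `Molecule` and a ligand `Molecule`; roles are stamped onto
#' the atoms so downstream interactive filtrations can partition them.
#'
#' @param protein,ligand `Molecule` objects.
#' @param id free-text label.
#' @return an object of class `ComplexStructure`.
#' @export
complex_structure <- function(protein, ligand, id = "") {
  stopifnot(inherits(protein, "Molecule"), inherits(ligand, "Molecule"))
  if (n_atoms(ligand) == 0) stop("ligand must be non-empty")
  protein$atoms$role <- rep("protein", nrow(protein$atoms))
  ligand$atoms$role <- rep("ligand", nrow(ligand$atoms))
  structure(list(protein = protein, ligand = ligand, id = id),
            class = "ComplexStructure")
}

#' @export
print.ComplexStructure <- function(x, ...) {
  cat(sprintf("<ComplexStructure '%s': %d protein + %d ligand atoms>\n",
              x$id, n_atoms(x$protein), n_atoms(x$ligand)))
  invisible(x)
}

# all atoms of a Molecule or ComplexStructure, roles preserved, protein first
all_atoms <- function(struct) {
  if (inherits(struct, "Molecule")) return(struct$atoms)
  if (inherits(struct, "ComplexStructure"))
    return(rbind(struct$protein$atoms, struct$ligand$atoms))
  stop("expected a Molecule or ComplexStructure")
}

#' Read a molecular structure file
#'
#' Reads PDB (via \pkg{bio3d}, one atom per ATOM/HETATM record) or Mol2
#' (`@<TRIPOS>ATOM` / `@<TRIPOS>BOND` blocks; the charge column populates
#' partial charges).  PDB waters (resid HOH) are skipped and only the first
#' alternate location of each atom is kept.
#'
#' @param path file path.
#' @param format `"pdb"` or `"mol2"`; guessed from the extension by default.
#' @param role role stamped onto the atoms (`"protein"` for PDB,
#'   `"ligand"` for Mol2 by default).
#' @param keep_waters keep HOH residues (PDB only)?
#' @return a [molecule()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mol2"),
                           role = NULL, keep_waters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mol2") "mol2" else "pdb"
  }
  if (format == "pdb") {
    read_pdb_file(path, role = if (is.null(role)) "protein" else role,
                  keep_waters = keep_waters)
  } else {
    read_mol2_file(path, role = if (is.null(role)) "ligand" else role)
  }
}

read_pdb_file <- function(path, role = "protein", keep_waters = FALSE) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (!keep_waters) at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), ,
                             drop = FALSE]
  # first altLoc only
  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep_alt <- alt %in% c("", "A", "1")
  at <- at[keep_alt, , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- gsub("[^A-Za-z].*$", "", trimws(at$elety))
    elem <- sub("^([A-Za-z])([a-z]?).*", "\\1\\2", elem)
  }
  elem <- normalize_element(elem)
  atoms <- data.frame(serial = at$eleno, element = elem,
                      x = at$x, y = at$y, z = at$z,
                      charge = NA_real_, role = role,
                      stringsAsFactors = FALSE)
  molecule(atoms, id = basename(path))
}

read_mol2_file <- function(path, role = "ligand") {
  lines <- readLines(path, warn = FALSE)
  ia <- grep("^@<TRIPOS>ATOM", lines)
  if (length(ia) == 0) stop("Mol2 parse error: no @<TRIPOS>ATOM block in ",
                            path)
  ib <- grep("^@<TRIPOS>BOND", lines)
  isec <- grep("^@<TRIPOS>", lines)
  block_end <- function(start) {
    nxt <- isec[isec > start]
    if (length(nxt) == 0) length(lines) else nxt[1] - 1L
  }
  atom_lines <- lines[seq(ia[1] + 1L, block_end(ia[1]))]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  parse_atom <- function(i) {
    f <- strsplit(trimws(atom_lines[i]), "\\s+")[[1]]
    if (length(f) < 6)
      stop(sprintf("Mol2 parse error at ATOM line %d: '%s'", i,
                   atom_lines[i]))
    xyz <- suppressWarnings(as.numeric(f[3:5]))
    if (any(is.na(xyz)))
      stop(sprintf("Mol2 parse error at ATOM line %d: bad coordinates", i))
    elem <- sub("\\..*$", "", f[6])
    chg <- if (length(f) >= 9) suppressWarnings(as.numeric(f[9])) else
      NA_real_
    list(serial = as.integer(f[1]), element = elem,
         x = xyz[1], y = xyz[2], z = xyz[3], charge = chg)
  }
  rows <- lapply(seq_along(atom_lines), parse_atom)
  atoms <- data.frame(serial = vapply(rows, `[[`, integer(1), "serial"),
                      element = normalize_element(
                        vapply(rows, `[[`, character(1), "element")),
                      x = vapply(rows, `[[`, numeric(1), "x"),
                      y = vapply(rows, `[[`, numeric(1), "y"),
                      z = vapply(rows, `[[`, numeric(1), "z"),
                      charge = vapply(rows, `[[`, numeric(1), "charge"),
                      role = role, stringsAsFactors = FALSE)
  bonds <- matrix(integer(), ncol = 2)
  if (length(ib) > 0) {
    bond_lines <- lines[seq(ib[1] + 1L, block_end(ib[1]))]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines) > 0) {
      bl <- lapply(seq_along(bond_lines), function(i) {
        f <- strsplit(trimws(bond_lines[i]), "\\s+")[[1]]
        if (length(f) < 3)
          stop(sprintf("Mol2 parse error at BOND line %d: '%s'", i,
                       bond_lines[i]))
        as.integer(f[2:3])
      })
      bonds <- do.call(rbind, bl)
      # bond block indexes atom serials; remap to row positions
      pos <- match(bonds, atoms$serial)
      if (any(is.na(pos))) stop("Mol2 bond references unknown atom serial")
      bonds <- matrix(pos, ncol = 2)
    }
  }
  molecule(atoms, bonds, id = basename(path))
}

normalize_element <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
}

#' Write a molecule to Mol2
#'
#' Emits minimal `@<TRIPOS>MOLECULE`, `ATOM` and `BOND` blocks, with the
#' partial-charge column populated, so generated fixtures round-trip through
#' [read_structure()].
#'
#' @param mol a [molecule()].
#' @param path output path.
#' @export
write_mol2 <- function(mol, path) {
  a <- mol$atoms
  n <- nrow(a)
  chg <- ifelse(is.na(a$charge), 0, a$charge)
  hdr <- c("@<TRIPOS>MOLECULE",
           if (nzchar(mol$id)) mol$id else "topomol",
           sprintf("%5d %5d", n, nrow(mol$bonds)),
           "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM")
  atom_lines <- sprintf("%7d %-4s %9.4f %9.4f %9.4f %-5s 1 LIG %9.4f",
                        seq_len(n), a$element, a$x, a$y, a$z, a$element, chg)
  bond_lines <- character(0)
  if (nrow(mol$bonds) > 0)
    bond_lines <- c("@<TRIPOS>BOND",
                    sprintf("%6d %5d %5d 1", seq_len(nrow(mol$bonds)),
                            mol$bonds[, 1], mol$bonds[, 2]))
  writeLines(c(hdr, atom_lines, bond_lines), path)
  invisible(path)
}

#' Write a molecule to PDB
#'
#' Thin wrapper over [bio3d::write.pdb()].
#'
#' @param mol a [molecule()].
#' @param path output path.
#' @export
write_pdb <- function(mol, path) {
  a <- mol$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords(mol))),
                   type = rep("ATOM", nrow(a)),
                   resno = rep(1L, nrow(a)), resid = rep("POC", nrow(a)),
                   eleno = a$serial, elety = a$element,
                   chain = rep("A", nrow(a)), elesy = a$element)
  invisible(path)
}

#' Build a covalent bond graph with hop distances
#'
#' The hop distance `D(i, j)` is the smallest number of covalent bonds to
#' travel from atom `i` to atom `j`, computed by breadth-first search;
#' unreachable pairs carry `Inf`.  With `mode = "distance_cutoff"` a bond is
#' declared whenever the inter-atomic distance is at most 1.3 times the sum
#' of covalent radii.
#'
#' @param mol a [molecule()].
#' @param mode `"from_records"` (use the molecule's bond list) or
#'   `"distance_cutoff"` (perceive bonds geometrically).
#' @param tolerance multiplier on the covalent-radius sum for
#'   `"distance_cutoff"`.
#' @return object of class `BondGraph` with elements `bonds` (matrix) and
#'   `D` (hop-distance matrix).
#' @export
build_bond_graph <- function(mol, mode = c("from_records", "distance_cutoff"),
                             tolerance = 1.3) {
  mode <- match.arg(mode)
  n <- n_atoms(mol)
  if (n == 0) stop("empty molecule")
  if (mode == "from_records") {
    bonds <- mol$bonds
  } else {
    xyz <- coords(mol)
    dm <- as.matrix(dist(xyz))
    rad <- covalent_radius(mol$atoms$element)
    thresh <- tolerance * outer(rad, rad, `+`)
    hit <- which(dm <= thresh & upper.tri(dm), arr.ind = TRUE)
    bonds <- matrix(as.integer(hit), ncol = 2)
  }
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {          # BFS from every source
    dist_s <- rep(Inf, n)
    dist_s[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist_s[w])) {
          dist_s[w] <- dist_s[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    D[s, ] <- dist_s
  }
  structure(list(bonds = bonds, D = D, n = n), class = "BondGraph")
}

#' Define an element-specific atom selection
#'
#' A selection names the element symbols kept on the protein side and/or the
#' ligand side.  The special symbols `"heavy"` (all elements except H) and
#' `"all"` are recognized.  Combination strings such as `"CNO"` or
#' `"CNOSPFClBrI"` are split on capital letters.
#'
#' @param protein,ligand character vectors of element symbols (or a single
#'   combination string), possibly empty.
#' @param label label; defaults to `"<protein>-<ligand>"` or the single
#'   non-empty side.
#' @return object of class `ElementSelection`.
#' @export
element_selection <- function(protein = character(), ligand = character(),
                              label = NULL) {
  pe <- parse_elements(protein)
  le <- parse_elements(ligand)
  if (length(pe) == 0 && length(le) == 0)
    stop("at least one of protein/ligand element sets must be non-empty")
  if (is.null(label)) {
    pl <- paste(pe, collapse = "")
    ll <- paste(le, collapse = "")
    label <- if (length(pe) > 0 && length(le) > 0) paste0(pl, "-", ll)
             else paste0(pl, ll)
  }
  structure(list(protein = pe, ligand = le, label = label),
            class = "ElementSelection")
}

# "CNOSPFClBrI" -> c("C","N","O","S","P","F","Cl","Br","I"); vectors pass
# through; "heavy"/"all" tokens are preserved
parse_elements <- function(x) {
  if (length(x) == 0) return(character())
  if (length(x) == 1 && !x %in% c("heavy", "all") && nchar(x) > 2) {
    m <- gregexpr("[A-Z][a-z]?", x)[[1]]
    return(regmatches(x, list(m))[[1]])
  }
  x
}

element_matches <- function(element, set) {
  if (length(set) == 0) return(rep(FALSE, length(element)))
  if ("all" %in% set) return(rep(TRUE, length(element)))
  if ("heavy" %in% set) return(element != "H")
  element %in% set
}

#' Select atoms by role and element
#'
#' Returns the atoms of `struct` whose (role, element) pair matches the
#' selection, preserving input order (protein atoms before ligand atoms for a
#' complex).  An empty result is valid.
#'
#' @param struct a [molecule()] or [complex_structure()].
#' @param sel an [element_selection()].
#' @return atom data frame (possibly with zero rows).
#' @export
select_atoms <- function(struct, sel) {
  stopifnot(inherits(sel, "ElementSelection"))
  at <- all_atoms(struct)
  keep <- (at$role == "protein" & element_matches(at$element, sel$protein)) |
          (at$role == "ligand" & element_matches(at$element, sel$ligand))
  at[keep, , drop = FALSE]
}

#' Truncate a complex to the binding-site neighbourhood
#'
#' Keeps every protein atom whose minimum distance to any ligand atom is at
#' most `cutoff` (default 12 Angstrom); the ligand is unchanged.  An empty
#' truncated protein is retained (with a warning).
#'
#' @param cx a [complex_structure()].
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return a [complex_structure()].
#' @export
truncate_binding_site <- function(cx, cutoff = 12) {
  stopifnot(inherits(cx, "ComplexStructure"), cutoff > 0)
  if (n_atoms(cx$ligand) == 0) stop("ligand must be non-empty")
  pc <- coords(cx$protein)
  lc <- coords(cx$ligand)
  if (nrow(pc) == 0) return(cx)
  dmin <- apply(pc, 1, function(p)
    min(sqrt(colSums((t(lc) - p)^2))))
  keep <- dmin <= cutoff
  if (!any(keep))
    warning("binding-site truncation removed every protein atom")
  prot <- cx$protein
  prot$atoms <- prot$atoms[keep, , drop = FALSE]
  keep_idx <- which(keep)
  if (nrow(prot$bonds) > 0) {
    inb <- prot$bonds[, 1] %in% keep_idx & prot$bonds[, 2] %in% keep_idx
    b <- prot$bonds[inb, , drop = FALSE]
    b[] <- match(b, keep_idx)
    prot$bonds <- matrix(as.integer(b), ncol = 2)
  }
  complex_structure(prot, cx$ligand, id = cx$id)
}
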