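# Filtration matrices: every distance-matrix variant the featurization uses.
# Excluded pairs (the d-infinity entries of the multi-level / interactive
# constructions) are represented as NA and never generate simplices, which is
# equivalent to any value above the filtration cap.

new_filtration_matrix <- function(values, scheme, axis_range) {
  n <- nrow(values)
  stopifnot(ncol(values) == n)
  dimnames(values) <- NULL
  diag(values) <- 0
  structure(list(n = n, values = values, scheme = scheme,
                 axis_range = axis_range),
            class = "FiltrationMatrix")
}

#' @export
print.FiltrationMatrix <- function(x, ...) {
  cat(sprintf("<FiltrationMatrix %dx%d, scheme=%s, axis=[%g, %g], %d excluded pairs>\n",
              x$n, x$n, x$scheme, x$axis_range[1], x$axis_range[2],
              sum(is.na(x$values[upper.tri(x$values)]))))
  invisible(x)
}

as_atoms <- function(x) {
  if (inherits(x, "Molecule") || inherits(x, "ComplexStructure"))
    return(all_atoms(x))
  as.data.frame(x)
}

atom_dist <- function(atoms) {
  d <- as.matrix(dist(as.matrix(atoms[, c("x", "y", "z")])))
  dimnames(d) <- NULL
  d
}

#' Euclidean filtration matrix
#'
#' Pairwise Euclidean distances in Angstrom; nothing excluded.
#'
#' @param atoms atom data frame (or a `Molecule`/`ComplexStructure`).
#' @return a `FiltrationMatrix` with scheme `"euclidean"`.
#' @export
euclidean_matrix <- function(atoms) {
  atoms <- as_atoms(atoms)
  if (nrow(atoms) < 1) stop("need at least one atom")
  v <- atom_dist(atoms)
  new_filtration_matrix(v, "euclidean", c(0, Inf))
}

#' Multi-level filtration matrix
#'
#' Excludes every pair within `level` covalent-bond hops (hop distance
#' `D(i, j) <= level`); all remaining pairs carry the Euclidean distance.
#' Level 1 removes bonded pairs, exposing non-covalent contacts in the
#' low-dimensional barcodes.
#'
#' @param atoms atom data frame or `Molecule`.
#' @param graph a [build_bond_graph()] covering the same atoms.
#' @param level bond-hop level, integer >= 1.
#' @return a `FiltrationMatrix` with scheme `"multilevel(level)"`.
#' @export
multilevel_matrix <- function(atoms, graph, level = 1) {
  atoms <- as_atoms(atoms)
  if (level < 1) stop("level must be >= 1")
  stopifnot(inherits(graph, "BondGraph"))
  if (graph$n != nrow(atoms)) stop("bond graph does not cover the atoms")
  v <- atom_dist(atoms)
  v[graph$D <= level] <- NA_real_
  new_filtration_matrix(v, sprintf("multilevel(%d)", level), c(0, Inf))
}

#' Interactive filtration matrix
#'
#' Keeps only cross-partition pairs (e.g. protein-ligand); within-partition
#' pairs are excluded.  The surviving entries come from `base`, so the
#' construction composes with the Euclidean or electrostatic matrices.
#'
#' @param base a `FiltrationMatrix` over the full atom set.
#' @param roles vector (length n) with exactly two distinct values, or a
#'   logical vector marking partition A1.
#' @return a `FiltrationMatrix` with scheme `"interactive"`.
#' @export
interactive_matrix <- function(base, roles) {
  stopifnot(inherits(base, "FiltrationMatrix"))
  if (is.logical(roles)) roles <- ifelse(roles, "A1", "A2")
  if (length(roles) != base$n) stop("roles must cover every atom")
  grp <- unique(roles)
  if (length(grp) != 2) stop("roles must define exactly two non-empty groups")
  cross <- outer(roles, roles, `!=`)
  v <- base$values
  v[!cross] <- NA_real_
  diag(v) <- 0
  new_filtration_matrix(v, paste0("interactive+", base$scheme),
                        base$axis_range)
}

#' Kernel specification for correlation filtrations
#'
#' @param family `"lorentz"`, `"exponential"` or `"electrostatic_sigmoid"`.
#' @param eta scale in Angstrom (scalar or per-pair matrix); must be > 0.
#' @param nu power of the Lorentz kernel; must be > 0.
#' @param c charge-coupling parameter for the electrostatic sigmoid
#'   (non-zero; positive values emphasize opposite-sign interactions).
#' @return object of class `KernelSpec`.
#' @export
kernel_spec <- function(family = c("lorentz", "exponential",
                                   "electrostatic_sigmoid"),
                        eta = NULL, nu = 2, c = 100) {
  family <- match.arg(family)
  if (!is.null(eta) && any(eta <= 0)) stop("eta must be positive")
  if (nu <= 0) stop("nu must be positive")
  if (family == "electrostatic_sigmoid" && c == 0)
    stop("c must be non-zero")
  structure(list(family = family, eta = eta, nu = nu, c = c),
            class = "KernelSpec")
}

# Lorentz radial basis function Phi(d; eta, nu) = 1 / (1 + (d / eta)^nu)
lorentz_phi <- function(d, eta, nu) 1 / (1 + (d / eta)^nu)

exponential_phi <- function(d, eta) exp(-d / eta)

#' Correlation-function filtration matrix
#'
#' Entries are `1 - Phi(d_ij, eta_ij)` with `Phi` a radial basis function
#' (Lorentz by default), mapping geometry onto the [0, 1] filtration axis;
#' pairs touching the excluded atom set `U` are dropped.  The default scale
#' `eta_ij` is the sum of the two atoms' van der Waals radii.
#'
#' @param atoms atom data frame or `Molecule`.
#' @param kernel a [kernel_spec()] (family `"lorentz"` or `"exponential"`).
#' @param exclude indices (or logical mask) of atoms in the excluded set U.
#' @return a `FiltrationMatrix` with axis range [0, 1].
#' @export
correlation_matrix <- function(atoms, kernel = kernel_spec("lorentz"),
                               exclude = integer()) {
  atoms <- as_atoms(atoms)
  n <- nrow(atoms)
  d <- atom_dist(atoms)
  eta <- kernel$eta
  if (is.null(eta)) {
    r <- vdw_radius(atoms$element)
    eta <- outer(r, r, `+`)
  }
  phi <- switch(kernel$family,
                lorentz = lorentz_phi(d, eta, kernel$nu),
                exponential = exponential_phi(d, eta),
                stop("unsupported kernel family for correlation_matrix"))
  v <- 1 - phi
  if (is.logical(exclude)) exclude <- which(exclude)
  if (length(exclude) > 0) {
    v[exclude, ] <- NA_real_
    v[, exclude] <- NA_real_
  }
  diag(v) <- 0
  new_filtration_matrix(v, sprintf("correlation(%s)", kernel$family),
                        c(0, 1))
}

#' Electrostatic correlation value
#'
#' The sigmoid `Phi = 1 / (1 + exp(-c q_i q_j / d))` rescales a pair of
#' partial charges and their separation onto (0, 1).  Weak interactions
#' (large `d` or near-zero charge product) give values near 0.5; with
#' `c > 0`, attractive (opposite-sign) pairs map into (0, 0.5) and repulsive
#' pairs into (0.5, 1).
#'
#' @param d distance in Angstrom (> 0).
#' @param qi,qj partial charges in elementary-charge units.
#' @param c non-zero coupling parameter (default 100).
#' @return value in (0, 1).
#' @export
electrostatic_value <- function(d, qi, qj, c = 100) {
  if (any(d <= 0)) stop("distance must be positive")
  if (c == 0) stop("c must be non-zero")
  1 / (1 + exp(-c * qi * qj / d))
}

#' Electrostatic filtration matrix
#'
#' Pairwise [electrostatic_value()] entries on the [0, 1] filtration axis.
#' Every atom must carry a partial charge.
#'
#' @param atoms atom data frame or `Molecule`.
#' @param c coupling parameter (default 100).
#' @return a `FiltrationMatrix` with scheme `"electrostatic(c)"`.
#' @export
electrostatic_matrix <- function(atoms, c = 100) {
  atoms <- as_atoms(atoms)
  q <- atoms$charge
  if (any(is.na(q)))
    stop("missing partial charge for atom(s): ",
         paste(atoms$serial[is.na(q)], collapse = ", "))
  d <- atom_dist(atoms)
  qq <- outer(q, q)
  v <- matrix(0, nrow(atoms), nrow(atoms))
  off <- upper.tri(d) | lower.tri(d)
  v[off] <- 1 / (1 + exp(-c * qq[off] / d[off]))
  new_filtration_matrix(v, sprintf("electrostatic(%g)", c), c(0, 1))
}

#' Per-atom rigidity index
#'
#' `mu_i = sum_{j != i} Phi(d_ij; eta_ij, nu)` with the Lorentz kernel; a
#' smooth measure of how tightly packed each atom's neighbourhood is.
#'
#' @param atoms atom data frame or `Molecule`.
#' @param kernel a [kernel_spec()] with family `"lorentz"`.
#' @return numeric vector of per-atom indices.
#' @export
rigidity_index <- function(atoms, kernel = kernel_spec("lorentz")) {
  if (kernel$family != "lorentz") stop("rigidity index uses the Lorentz kernel")
  atoms <- as_atoms(atoms)
  n <- nrow(atoms)
  if (n == 1) return(0)
  d <- atom_dist(atoms)
  eta <- kernel$eta
  if (is.null(eta)) {
    r <- vdw_radius(atoms$element)
    eta <- outer(r, r, `+`)
  }
  phi <- lorentz_phi(d, eta, kernel$nu)
  diag(phi) <- 0
  unname(rowSums(phi))
}

#' Charge density field evaluator
#'
#' `mu_c(r) = sum_j q_j exp(-||r - r_j|| / eta_j)`: a scalar field built from
#' exponentially screened partial charges, evaluated at arbitrary positions.
#'
#' @param atoms atom data frame or `Molecule` with charges.
#' @param r a 3-vector or matrix of positions (rows).
#' @param eta per-atom scale(s) in Angstrom (recycled).
#' @return numeric vector of field values at the positions.
#' @export
charge_density <- function(atoms, r, eta = 1) {
  atoms <- as_atoms(atoms)
  q <- atoms$charge
  if (any(is.na(q))) stop("missing partial charge")
  eta <- rep_len(eta, nrow(atoms))
  r <- matrix(r, ncol = 3)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  apply(r, 1, function(p) {
    dd <- sqrt(colSums((t(xyz) - p)^2))
    sum(q * exp(-dd / eta))
  })
}

#' Serialize a filtration matrix to TSV
#'
#' Dense tab-separated values with the token `INF` for excluded pairs and a
#' `#scheme` header line.
#'
#' @param m a `FiltrationMatrix`.
#' @param path output path.
#' @export
write_filtration_tsv <- function(m, path) {
  stopifnot(inherits(m, "FiltrationMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#scheme\t%s\t%g\t%g", m$scheme,
                     m$axis_range[1], m$axis_range[2]), con)
  v <- m$values
  txt <- apply(v, 1, function(row) {
    s <- formatC(row, format = "g", digits = 10)
    s[is.na(row)] <- "INF"
    paste(s, collapse = "\t")
  })
  writeLines(txt, con)
  invisible(path)
}

#' Read a filtration matrix from TSV
#'
#' @param path file written by [write_filtration_tsv()].
#' @return a `FiltrationMatrix`.
#' @export
read_filtration_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  vals <- lapply(lines[-1], function(l) {
    s <- strsplit(l, "\t")[[1]]
    out <- suppressWarnings(as.numeric(s))
    out[s == "INF"] <- NA_real_
    out
  })
  v <- do.call(rbind, vals)
  new_filtration_matrix(v, hdr[2],
                        c(as.numeric(hdr[3]), as.numeric(hdr[4])))
}
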