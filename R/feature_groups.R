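# Named feature-group recipes: each group fixes a complex type, filtration
# scheme, homology dimensions, element combinations, vectorizer and bins,
# and assembles a deterministic named feature vector for a structure.

.group_registry <- new.env(parent = emptyenv())

#' Register a feature-group recipe
#'
#' @param id group identifier (e.g. `"A-B012-E-S"`).
#' @param config list with fields `target` (`"ligand"` or `"complex"`),
#'   `complex` (`"rips"`/`"alpha"`), `scheme`, `dims`, `cap`, `combos`,
#'   `vectorizer` (`"counts"`/`"stats"`/`"slice"`), and optionally `bins`,
#'   `slice_bins`, `level`, `c`.
#' @export
register_feature_group <- function(id, config) {
  config$id <- id
  assign(id, config, envir = .group_registry)
  invisible(id)
}

#' Look up a registered feature group
#'
#' @param id group identifier.
#' @return the group config list.
#' @export
feature_group <- function(id) {
  if (!exists(id, envir = .group_registry))
    stop("unknown feature group: ", id)
  get(id, envir = .group_registry)
}

#' List registered feature groups
#' @return character vector of group ids.
#' @export
feature_groups <- function() sort(ls(.group_registry))

register_default_groups <- function() {
  lig_alpha <- list(target = "ligand", complex = "alpha",
                    scheme = "euclidean", dims = 0:2, cap = 5,
                    combos = .lig32)
  register_feature_group("A-B012-E-C", c(lig_alpha, list(
    vectorizer = "counts", bins = uniform_bins(0, 5, 50))))
  register_feature_group("A-B012-E-S", c(lig_alpha, list(
    vectorizer = "stats")))
  register_feature_group("A-B012-E-SS", c(lig_alpha, list(
    vectorizer = "slice", slice_bins = uniform_bins(0, 5, 10))))
  register_feature_group("R-B012-E-S", list(
    target = "ligand", complex = "rips", scheme = "euclidean",
    dims = 0:2, cap = 12, combos = .lig36, vectorizer = "stats"))
  register_feature_group("R-B012-M1-S", list(
    target = "ligand", complex = "rips", scheme = "multilevel", level = 1,
    dims = 0:2, cap = 12, combos = .lig36, vectorizer = "stats"))
  int_bins <- bin_spec(c(0, 2.5, 3, 3.5, 4.5, 6),
                       c(2.5, 3, 3.5, 4.5, 6, 12))
  register_feature_group("R-B0-I-C", list(
    target = "complex", complex = "rips", scheme = "interactive",
    dims = 0, cap = 12, combos = pair_combos(.prot8, .lig20),
    vectorizer = "counts", bins = int_bins))
  register_feature_group("R-B0-I-BP", list(
    target = "complex", complex = "rips", scheme = "interactive",
    dims = 0, cap = 12, combos = pair_combos(.prot4, .lig9),
    vectorizer = "counts", bins = int_bins))
  ci <- list(target = "complex", complex = "rips",
             scheme = "electrostatic_interactive", c = 100,
             dims = 0, cap = 1, combos = pair_combos(.prot5, .lig10))
  register_feature_group("R-B0-CI-C", c(ci, list(
    vectorizer = "counts",
    bins = uniform_bins(0, 1, 10, closure = "left_open"))))
  register_feature_group("R-B0-CI-S", c(ci, list(vectorizer = "stats")))
  register_feature_group("A-B12-E-S", list(
    target = "complex", complex = "alpha", scheme = "euclidean",
    dims = 1:2, cap = 12, combos = c("heavy", "C"), vectorizer = "stats"))
}

# row indices (into all_atoms order) matched by a selection
select_atom_indices <- function(struct, sel) {
  at <- all_atoms(struct)
  which((at$role == "protein" & element_matches(at$element, sel$protein)) |
        (at$role == "ligand" & element_matches(at$element, sel$ligand)))
}

# barcode of one element combination under a group config
combo_barcode <- function(struct, group, combo, bond_graph = NULL,
                          protein_only = FALSE) {
  max_dim <- max(group$dims)
  cap <- group$cap
  if (group$target == "ligand" || is.character(combo)) {
    # single-structure selection (combo is a combination string or token)
    if (group$target == "ligand" && inherits(struct, "ComplexStructure"))
      struct <- struct$ligand
    if (inherits(struct, "ComplexStructure")) {
      if (protein_only) struct <- struct$protein
      sel <- element_selection(protein = combo, ligand = combo,
                               label = combo)
    } else {
      role <- struct$atoms$role[1]
      sel <- if (identical(role, "protein"))
        element_selection(protein = combo, label = combo)
      else element_selection(ligand = combo, label = combo)
    }
    idx <- select_atom_indices(struct, sel)
    at <- all_atoms(struct)[idx, , drop = FALSE]
    prov <- list(id = if (!is.null(struct$id)) struct$id else "",
                 selection = combo)
    if (nrow(at) == 0)
      return(empty_barcode(cap, group$complex, prov))
    if (group$complex == "alpha") {
      xyz <- as.matrix(at[, c("x", "y", "z")])
      if (nrow(at) > 1 && max(dist(xyz)) < 1e-9)
        return(empty_barcode(cap, "alpha", prov))
      return(alpha_persistence(xyz, max_dim, cap, prov))
    }
    m <- if (identical(group$scheme, "multilevel")) {
      if (is.null(bond_graph)) bond_graph <- molecule_bond_graph(struct)
      sub_multilevel_matrix(at, bond_graph, idx, group$level %||% 1)
    } else euclidean_matrix(at)
    return(rips_persistence(m, max_dim, cap, prov))
  }
  # interactive protein-ligand pair (combo: list/row with protein, ligand)
  sel <- element_selection(protein = combo$protein, ligand = combo$ligand,
                           label = combo$label)
  at <- select_atoms(struct, sel)
  prov <- list(id = struct$id, selection = combo$label)
  np <- sum(at$role == "protein")
  nl <- sum(at$role == "ligand")
  if (np == 0 || nl == 0 || nrow(at) == 0)
    return(empty_barcode(cap, "rips", prov))
  base <- if (identical(group$scheme, "electrostatic_interactive"))
    electrostatic_matrix(at, c = group$c %||% 100)
  else euclidean_matrix(at)
  m <- interactive_matrix(base, at$role)
  rips_persistence(m, max(group$dims), cap, prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

molecule_bond_graph <- function(mol) {
  if (nrow(mol$bonds) > 0) build_bond_graph(mol, "from_records")
  else build_bond_graph(mol, "distance_cutoff")
}

# multilevel matrix on a subset of atoms, hop distances taken on the full
# molecular bond graph (non-selected atoms still conduct bond paths)
sub_multilevel_matrix <- function(at, graph, idx, level) {
  v <- atom_dist(at)
  Dsub <- graph$D[idx, idx, drop = FALSE]
  v[Dsub <= level] <- NA_real_
  new_filtration_matrix(v, sprintf("multilevel(%d)", level), c(0, Inf))
}

vectorize_barcode <- function(b, group) {
  out <- numeric(0)
  for (dim in group$dims) {
    if (identical(group$vectorizer, "counts")) {
      cc <- counts_in_bins(b, group$bins, dim)
      nb <- seq_len(n_bins(group$bins))
      if (dim == 0) {
        # dim-0 births are identically zero and every live bar overlaps
        # every bin, so only the death counts are informative features
        v <- setNames(cc$deaths, paste0("death.bin", nb))
      } else {
        v <- c(setNames(cc$births, paste0("birth.bin", nb)),
               setNames(cc$deaths, paste0("death.bin", nb)),
               setNames(cc$persistences, paste0("pers.bin", nb)))
      }
    } else if (identical(group$vectorizer, "stats")) {
      v <- barcode_statistics(b, dim)
    } else if (identical(group$vectorizer, "slice")) {
      v <- c(slice_statistics(b, "death", group$slice_bins, dim),
             slice_statistics(b, "birth", group$slice_bins, dim),
             slice_statistics(b, "persistence", group$slice_bins, dim))
    } else stop("unknown vectorizer: ", group$vectorizer)
    names(v) <- paste0("d", dim, ".", names(v))
    out <- c(out, v)
  }
  out
}

#' Assemble the feature vector of a registered group
#'
#' Runs the group's full pipeline — element-specific atom selection,
#' filtration matrix, persistence, vectorization — for every combination in
#' the group's list and concatenates the blocks deterministically.
#'
#' @param struct a [molecule()] (ligand groups) or [complex_structure()]
#'   (complex groups).
#' @param group a group id (see [feature_groups()]) or config list.
#' @return object of class `FeatureBlock`: list with `values` (named
#'   numeric), `schema` (names) and `group_id`.
#' @export
assemble_features <- function(struct, group) {
  if (is.character(group)) group <- feature_group(group)
  if (group$target == "complex" && !inherits(struct, "ComplexStructure"))
    stop("feature group ", group$id, " requires a ComplexStructure")
  bond_graph <- NULL
  if (identical(group$scheme, "multilevel")) {
    mol <- if (inherits(struct, "ComplexStructure")) struct$ligand else
      struct
    bond_graph <- molecule_bond_graph(mol)
  }
  blocks <- list()
  combos <- group$combos
  if (is.data.frame(combos)) {
    for (i in seq_len(nrow(combos))) {
      cb <- combo_barcode(struct, group, combos[i, ])
      v <- vectorize_barcode(cb, group)
      names(v) <- paste0(combos$label[i], ".", names(v))
      blocks[[i]] <- v
    }
  } else {
    for (i in seq_along(combos)) {
      cb <- combo_barcode(struct, group, combos[i], bond_graph)
      v <- vectorize_barcode(cb, group)
      names(v) <- paste0(combos[i], ".", names(v))
      blocks[[i]] <- v
    }
  }
  values <- do.call(c, blocks)
  structure(list(values = values, schema = names(values),
                 group_id = group$id), class = "FeatureBlock")
}

#' @export
print.FeatureBlock <- function(x, ...) {
  cat(sprintf("<FeatureBlock %s: %d features>\n", x$group_id,
              length(x$values)))
  invisible(x)
}

#' Feature matrix for a set of structures
#'
#' @param structs list of structures.
#' @param groups character vector of group ids; blocks are concatenated
#'   per structure.
#' @return numeric matrix, one row per structure, with schema column names.
#' @export
topo_feature_matrix <- function(structs, groups) {
  rows <- lapply(structs, function(s) {
    do.call(c, lapply(groups, function(g) assemble_features(s, g)$values))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- NULL
  mat
}

#' Write a feature block (or matrix) to CSV
#'
#' @param x a `FeatureBlock` or a feature matrix.
#' @param path output path.
#' @export
write_feature_csv <- function(x, path) {
  if (inherits(x, "FeatureBlock"))
    x <- matrix(x$values, nrow = 1, dimnames = list(NULL, x$schema))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' 2-D topological image of a protein-ligand complex
#'
#' Convenience wrapper computing per-combination alpha-complex barcodes for
#' the complex and for the protein alone, then stacking the 16-channel
#' binned-count image (see [build_2d_image()]).
#'
#' @param cx a [complex_structure()].
#' @param bins spatial bins (default 120 equal bins on \[0, 12\] Angstrom).
#' @param combos combination data frame (default the 128-pair list).
#' @param ordering combination labels most-important-first; defaults to the
#'   stored list order (importance orders learned on a task can be passed
#'   through unchanged at inference).
#' @return a `TopoImage` of dimension bins x combinations x 16.
#' @export
complex_2d_image <- function(cx, bins = uniform_bins(0, 12, 120),
                             combos = topo_combinations("image128"),
                             ordering = combos$label) {
  stopifnot(inherits(cx, "ComplexStructure"))
  group <- list(target = "complex", complex = "alpha", scheme = "euclidean",
                dims = 0:2, cap = max(bins$r), id = "2d-image")
  bc_cx <- list(); bc_pr <- list()
  for (i in seq_len(nrow(combos))) {
    lab <- combos$label[i]
    sel <- element_selection(protein = combos$protein[i],
                             ligand = combos$ligand[i], label = lab)
    idx <- select_atom_indices(cx, sel)
    at <- all_atoms(cx)[idx, , drop = FALSE]
    bc_cx[[lab]] <- if (nrow(at) == 0) empty_barcode(group$cap, "alpha")
      else alpha_persistence(as.matrix(at[, c("x", "y", "z")]), 2,
                             group$cap)
    atp <- at[at$role == "protein", , drop = FALSE]
    bc_pr[[lab]] <- if (nrow(atp) == 0) empty_barcode(group$cap, "alpha")
      else alpha_persistence(as.matrix(atp[, c("x", "y", "z")]), 2,
                             group$cap)
  }
  build_2d_image(bc_cx, bins, ordering, protein_barcodes = bc_pr)
}
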