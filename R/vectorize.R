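# Barcode vectorization: counts in bins, barcode statistics, persistence
# diagram slice statistics, multi-channel 2-D topological images, and the
# registry of named feature-group recipes.

#' Bin specification on the filtration axis
#'
#' @param l,r numeric vectors of left/right bin edges (ordered,
#'   non-overlapping interiors).
#' @param closure `"right_open"` (`[l, r)`, last bin closed) or
#'   `"left_open"` (`(l, r]`).
#' @return object of class `BinSpec`.
#' @export
bin_spec <- function(l, r, closure = c("right_open", "left_open")) {
  closure <- match.arg(closure)
  stopifnot(length(l) == length(r), all(l < r))
  if (length(l) > 1 && any(l[-1] < r[-length(r)] - 1e-12))
    stop("bins must not overlap")
  structure(list(l = l, r = r, closure = closure), class = "BinSpec")
}

#' Uniform bins over an interval
#'
#' @param lo,hi interval bounds.
#' @param n number of equal-length bins.
#' @param closure see [bin_spec()].
#' @return a [bin_spec()].
#' @export
uniform_bins <- function(lo, hi, n, closure = "right_open") {
  br <- seq(lo, hi, length.out = n + 1)
  bin_spec(br[-(n + 1)], br[-1], closure)
}

n_bins <- function(bins) length(bins$l)

bin_member <- function(x, bins) {
  # n_values x n_bins logical membership matrix; infinite x in no bin
  nb <- n_bins(bins)
  out <- matrix(FALSE, length(x), nb)
  for (i in seq_len(nb)) {
    if (bins$closure == "right_open") {
      hit <- x >= bins$l[i] & (if (i == nb) x <= bins$r[i] else x < bins$r[i])
    } else {
      hit <- x > bins$l[i] & x <= bins$r[i]
    }
    out[, i] <- hit & is.finite(x)
  }
  out
}

#' Counts of births, deaths and persistences in bins
#'
#' For each bin, counts the bars whose birth falls in the bin, whose death
#' falls in the bin, and whose interval overlaps the bin (birth at most the
#' right edge and death at least the left edge).  OPEN bars fall in no death
#' bin but overlap every bin to the right of their birth.
#'
#' @param b a [barcode()].
#' @param bins a [bin_spec()].
#' @param dim homology dimension to count.
#' @return list with numeric vectors `births`, `deaths`, `persistences`.
#' @export
counts_in_bins <- function(b, bins, dim = 0) {
  bars <- bars_of_dim(b, dim)
  nb <- n_bins(bins)
  if (nrow(bars) == 0)
    return(list(births = rep(0, nb), deaths = rep(0, nb),
                persistences = rep(0, nb)))
  births <- colSums(bin_member(bars$birth, bins))
  deaths <- colSums(bin_member(bars$death, bins))
  overlap <- vapply(seq_len(nb), function(i)
    sum(bars$birth <= bins$r[i] & bars$death >= bins$l[i]), numeric(1))
  list(births = births, deaths = deaths, persistences = overlap)
}

stat6 <- function(x) {
  if (length(x) == 0) return(c(avg = 0, std = 0, max = 0, min = 0,
                               sum = 0, cnt = 0))
  c(avg = mean(x), std = sqrt(mean((x - mean(x))^2)), max = max(x),
    min = min(x), sum = sum(x), cnt = length(x))
}

#' Barcode statistics features
#'
#' Per-dimension statistics of the Birth, Death and Persistence multisets:
#' average, population standard deviation, max, min, sum and count (6 each);
#' the Persistence block carries two extra terms, the birth and death of the
#' longest bar (8).  Dimension 0 contributes the Death block only (births
#' are identically zero).  OPEN bars are capped at the barcode cap first;
#' empty sets produce all-zero blocks.
#'
#' @param b a [barcode()].
#' @param dim homology dimension.
#' @return named numeric vector (6 values for dim 0, 20 otherwise).
#' @export
barcode_statistics <- function(b, dim = 0) {
  bars <- bars_of_dim(b, dim)
  if (nrow(bars) > 0 && any(is.infinite(bars$death))) {
    if (!is.finite(b$cap)) stop("OPEN bars require a finite cap")
    bars$death <- pmin(bars$death, b$cap)
  }
  death <- stat6(bars$death)
  names(death) <- paste0("death.", names(death))
  if (dim == 0) return(death)
  birth <- stat6(bars$birth)
  names(birth) <- paste0("birth.", names(birth))
  pers_vals <- bars$death - bars$birth
  pers <- stat6(pers_vals)
  if (nrow(bars) > 0) {
    longest <- which.max(pers_vals)
    extra <- c(bars$birth[longest], bars$death[longest])
  } else extra <- c(0, 0)
  pers <- c(pers, extra)
  names(pers) <- paste0("pers.", c(names(pers)[1:6], "longest.birth",
                                   "longest.death"))
  c(birth, death, pers)
}

#' Persistence-diagram slice statistics
#'
#' Partitions the bars of one dimension into slices along the chosen axis
#' and summarizes the complementary coordinate(s) of each slice with the
#' 6-value statistics block: death-sliced bars are summarized by their
#' births, birth-sliced by their deaths, persistence-sliced by both.
#'
#' @param b a [barcode()].
#' @param axis `"birth"`, `"death"` or `"persistence"`.
#' @param bins a [bin_spec()] slicing the chosen axis.
#' @param dim homology dimension.
#' @return named numeric vector (6 or 12 values per slice).
#' @export
slice_statistics <- function(b, axis = c("death", "birth", "persistence"),
                             bins, dim = 0) {
  axis <- match.arg(axis)
  bars <- bars_of_dim(b, dim)
  if (nrow(bars) > 0 && any(is.infinite(bars$death))) {
    if (!is.finite(b$cap)) stop("OPEN bars require a finite cap")
    bars$death <- pmin(bars$death, b$cap)
  }
  key <- switch(axis, birth = bars$birth, death = bars$death,
                persistence = bars$death - bars$birth)
  member <- bin_member(key, bins)
  out <- numeric(0)
  for (i in seq_len(n_bins(bins))) {
    sl <- bars[member[, i], , drop = FALSE]
    if (axis == "death") {
      blk <- stat6(sl$birth)
      names(blk) <- paste0("slice", i, ".birth.", names(blk))
    } else if (axis == "birth") {
      blk <- stat6(sl$death)
      names(blk) <- paste0("slice", i, ".death.", names(blk))
    } else {
      b1 <- stat6(sl$birth); b2 <- stat6(sl$death)
      names(b1) <- paste0("slice", i, ".birth.", names(b1))
      names(b2) <- paste0("slice", i, ".death.", names(b2))
      blk <- c(b1, b2)
    }
    out <- c(out, blk)
  }
  out
}

# ---- element combination lists -------------------------------------------

.lig16 <- c("C", "N", "O", "S", "CN", "CO", "CS", "NO", "NS", "OS",
            "CNO", "CNS", "COS", "NOS", "CNOS", "CNOSPFClBrI")
.lig32 <- c(.lig16, paste0(.lig16, "H"))
.lig36 <- c(.lig32, "CCl", "CClH", "CBr", "CBrH")
.knn5 <- c("CNOS", "CNOSPFClBrI", "NOH", "CNO", "CNOSPFClBrIH")
.prot8 <- c("C", "N", "O", "S", "CN", "CO", "NO", "CNO")
.lig20 <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "CN", "CO",
            "CS", "NO", "NS", "OS", "CNO", "CNS", "COS", "NOS", "CNOS")
.prot4 <- c("C", "N", "O", "S")
.lig9 <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
.prot5 <- c("C", "N", "O", "S", "H")
.lig10 <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "H")
.img_prot8 <- c("C", "N", "O", "CN", "CO", "NO", "CNO", "CNOS")
.img_lig16 <- c("C", "N", "O", "S", "CN", "CO", "CS", "NO", "NS", "OS",
                "CNO", "CNS", "COS", "NOS", "CNOS", "CNOSPFClBrI")

pair_combos <- function(protein, ligand) {
  g <- expand.grid(ligand = ligand, protein = protein,
                   stringsAsFactors = FALSE)[, 2:1]
  g <- g[order(match(g$protein, protein), match(g$ligand, ligand)), ]
  g$label <- paste0(g$protein, "-", g$ligand)
  rownames(g) <- NULL
  g
}

#' Element combination lists
#'
#' The registered element-combination lists used by the feature-group
#' recipes: 32 and 36 single-molecule combinations, the 5 combinations used
#' with barcode-space KNN, the 160 (8 x 20) and 36 (4 x 9) interactive
#' protein-ligand pairs, the 50 (5 x 10) electrostatic pairs, and the
#' 128 (8 x 16) pairs of the 2-D image representation.
#'
#' @param name one of `"ligand32"`, `"ligand36"`, `"knn5"`,
#'   `"interactive160"`, `"interactive36"`, `"electrostatic50"`,
#'   `"image128"`.
#' @return a character vector of combination strings, or a data frame with
#'   columns `protein`, `ligand`, `label` for paired lists.
#' @export
topo_combinations <- function(name) {
  switch(name,
         ligand32 = .lig32,
         ligand36 = .lig36,
         knn5 = .knn5,
         interactive160 = pair_combos(.prot8, .lig20),
         interactive36 = pair_combos(.prot4, .lig9),
         electrostatic50 = pair_combos(.prot5, .lig10),
         image128 = pair_combos(.img_prot8, .img_lig16),
         stop("unknown combination list: ", name))
}

# ---- 2-D topological image ----------------------------------------------

image_channels <- function(b, bins) {
  c0 <- counts_in_bins(b, bins, 0)
  c1 <- counts_in_bins(b, bins, 1)
  c2 <- counts_in_bins(b, bins, 2)
  cbind(c0$deaths, c0$persistences,
        c1$births, c1$deaths, c1$persistences,
        c2$births, c2$deaths, c2$persistences)
}

.channel_names <- c("d0.death", "d0.pers", "d1.birth", "d1.death",
                    "d1.pers", "d2.birth", "d2.death", "d2.pers")

#' Build a multi-channel 2-D topological image
#'
#' Stacks per-combination binned barcode counts into a
#' (bins x combinations x channels) tensor.  The eight base channels are the
#' dim-0 death and persistence counts and the dim-1/dim-2 birth, death and
#' persistence counts.  In complex mode, eight further channels hold the
#' difference between the complex counts and the protein-only counts,
#' giving 16 channels in total.
#'
#' @param barcodes named list: combination label -> [barcode()] (holding
#'   dims 0-2) of the complex (or single structure).
#' @param bins a [bin_spec()] (the spatial-scale axis).
#' @param ordering character vector of combination labels, most important
#'   first; must cover all provided combinations.
#' @param protein_barcodes optional named list of protein-only barcodes
#'   (same labels); supplying it switches on complex mode.
#' @return object of class `TopoImage`: numeric array
#'   (bins x combinations x channels) with dimnames.
#' @export
build_2d_image <- function(barcodes, bins, ordering = names(barcodes),
                           protein_barcodes = NULL) {
  if (!all(ordering %in% names(barcodes)))
    stop("missing combination(s): ",
         paste(setdiff(ordering, names(barcodes)), collapse = ", "))
  if (!all(names(barcodes) %in% ordering))
    stop("ordering must cover all provided combinations")
  nch <- if (is.null(protein_barcodes)) 8L else 16L
  nb <- n_bins(bins)
  out <- array(0, dim = c(nb, length(ordering), nch))
  ch_names <- .channel_names
  if (nch == 16L) ch_names <- c(ch_names, paste0("diff.", .channel_names))
  dimnames(out) <- list(NULL, ordering, ch_names)
  for (j in seq_along(ordering)) {
    lab <- ordering[j]
    cx <- image_channels(barcodes[[lab]], bins)
    out[, j, 1:8] <- cx
    if (nch == 16L) {
      if (!lab %in% names(protein_barcodes))
        stop("missing combination(s) in protein barcodes: ", lab)
      out[, j, 9:16] <- cx - image_channels(protein_barcodes[[lab]], bins)
    }
  }
  structure(out, class = c("TopoImage", "array"))
}

#' Write a topological image with a JSON sidecar
#'
#' The tensor is written as a flat numeric binary (double, native endian)
#' with a JSON sidecar recording dimensions, bins, ordering and channels.
#'
#' @param img a `TopoImage`.
#' @param path output path for the tensor; the sidecar is `<path>.json`.
#' @param bins the [bin_spec()] used to build the image.
#' @export
write_topo_image <- function(img, path, bins = NULL) {
  con <- file(path, "wb")
  writeBin(as.numeric(img), con)
  close(con)
  meta <- list(dim = dim(img), combinations = dimnames(img)[[2]],
               channels = dimnames(img)[[3]])
  if (!is.null(bins)) meta$bins <- list(l = bins$l, r = bins$r)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
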