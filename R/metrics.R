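# Barcode-space metrics.  The optimal matching is solved exactly: the
# Wasserstein distance through a Hungarian assignment on the
# diagonal-augmented cost matrix, the bottleneck distance through a binary
# search over candidate penalties with a bipartite-matching feasibility
# test.  An exhaustive-bijection oracle backs both in the test suite.

metric_bars <- function(b, dim = NULL) {
  bars <- if (inherits(b, "Barcode")) {
    bb <- b$bars
    if (!is.null(dim)) bb <- bb[bb$dim == dim, , drop = FALSE]
    if (any(is.infinite(bb$death))) {
      if (!is.finite(b$cap))
        stop("OPEN bars require a finite cap before metric computation")
      bb$death <- pmin(bb$death, b$cap)
    }
    bb
  } else as.data.frame(b)
  if (nrow(bars) > 0 && any(!is.finite(bars$death)))
    stop("metrics operate on capped (closed) bars")
  bars[, c("birth", "death"), drop = FALSE]
}

#' l-infinity gap between two bars
#'
#' `max(|b2 - b1|, |d2 - d1|)` for closed bars.
#'
#' @param I1,I2 bars: numeric `c(birth, death)` (or 1-row data frames).
#' @return non-negative value.
#' @export
bar_gap <- function(I1, I2) {
  I1 <- as.numeric(I1)[1:2]; I2 <- as.numeric(I2)[1:2]
  if (any(!is.finite(c(I1, I2)))) stop("bars must be closed (finite)")
  max(abs(I2[1] - I1[1]), abs(I2[2] - I1[2]))
}

#' Half-persistence (diagonal penalty) of a bar
#'
#' `(death - birth) / 2`: the cost of leaving the bar unmatched.
#'
#' @param I bar: numeric `c(birth, death)`.
#' @return non-negative value.
#' @export
bar_diag <- function(I) {
  I <- as.numeric(I)[1:2]
  if (any(!is.finite(I))) stop("bars must be closed (finite)")
  (I[2] - I[1]) / 2
}

gap_matrix <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0)
    return(matrix(numeric(), nrow(A), nrow(B)))
  gb <- outer(A$birth, B$birth, function(x, y) abs(y - x))
  gd <- outer(A$death, B$death, function(x, y) abs(y - x))
  pmax(gb, gd)
}

#' Penalty of a matching between two barcodes
#'
#' For a partial bijection `theta`, matched bars pay their l-infinity gap
#' and unmatched bars on either side pay their half-persistence; with finite
#' order `p` penalties enter as a p-power sum, with `p = Inf` as a maximum.
#'
#' @param b1,b2 barcodes (or bar data frames); OPEN bars must be capped.
#' @param theta integer vector over bars of `b1`: index of the matched bar
#'   in `b2`, or `NA` for unmatched.
#' @param p order (finite) or `Inf` for the bottleneck form.
#' @param dim optional homology dimension filter.
#' @return the penalty value (p-power sum for finite p).
#' @export
matching_penalty <- function(b1, b2, theta, p = 2, dim = NULL) {
  A <- metric_bars(b1, dim); B <- metric_bars(b2, dim)
  if (length(theta) != nrow(A)) stop("theta must cover every bar of b1")
  matched <- which(!is.na(theta))
  if (anyDuplicated(theta[matched]) > 0) stop("theta must be injective")
  gaps <- vapply(matched, function(i)
    bar_gap(A[i, ], B[theta[i], ]), numeric(1))
  lam1 <- vapply(setdiff(seq_len(nrow(A)), matched), function(i)
    bar_diag(A[i, ]), numeric(1))
  lam2 <- vapply(setdiff(seq_len(nrow(B)), theta[matched]), function(j)
    bar_diag(B[j, ]), numeric(1))
  if (is.infinite(p)) {
    vals <- c(gaps, lam1, lam2)
    if (length(vals) == 0) 0 else max(vals)
  } else {
    sum(gaps^p) + sum(lam1^p) + sum(lam2^p)
  }
}

#' Wasserstein distance between barcodes
#'
#' `d_p = (min_theta P_p(theta))^(1/p)` over all partial bijections; solved
#' exactly by optimal assignment on the diagonal-augmented cost matrix.
#' Default order `p = 2`.
#'
#' @param b1,b2 barcodes (or bar data frames); OPEN bars are capped at the
#'   barcode cap.
#' @param p finite order.
#' @param dim optional homology dimension filter.
#' @return the distance.
#' @export
wasserstein_distance <- function(b1, b2, p = 2, dim = NULL) {
  A <- metric_bars(b1, dim); B <- metric_bars(b2, dim)
  n <- nrow(A); m <- nrow(B)
  if (n == 0 && m == 0) return(0)
  lamA <- if (n) vapply(seq_len(n), function(i) bar_diag(A[i, ]),
                        numeric(1)) else numeric(0)
  lamB <- if (m) vapply(seq_len(m), function(j) bar_diag(B[j, ]),
                        numeric(1)) else numeric(0)
  if (n == 0) return(sum(lamB^p)^(1 / p))
  if (m == 0) return(sum(lamA^p)^(1 / p))
  big <- (sum(c(gap_matrix(A, B)^p, lamA^p, lamB^p)) + 1) * 2
  sz <- n + m
  cost <- matrix(0, sz, sz)              # bottom-right block: diag-diag, 0
  cost[seq_len(n), seq_len(m)] <- gap_matrix(A, B)^p
  cost[seq_len(n), m + seq_len(n)] <- big
  cost[cbind(seq_len(n), m + seq_len(n))] <- lamA^p
  cost[n + seq_len(m), seq_len(m)] <- big
  cost[cbind(n + seq_len(m), seq_len(m))] <- lamB^p
  hungarian_cpp(cost)^(1 / p)
}

# is there a perfect matching in the augmented structure with threshold t?
bottleneck_feasible <- function(gm, lamA, lamB, t) {
  n <- length(lamA); m <- length(lamB)
  sz <- n + m
  allowed <- matrix(FALSE, sz, sz)
  if (n && m) allowed[seq_len(n), seq_len(m)] <- gm <= t
  if (n) allowed[cbind(seq_len(n), m + seq_len(n))] <- lamA <= t
  if (m) allowed[cbind(n + seq_len(m), seq_len(m))] <- lamB <= t
  allowed[n + seq_len(m), m + seq_len(n)] <- TRUE
  # Kuhn's augmenting-path maximum matching
  match_col <- rep(NA_integer_, sz)
  try_row <- function(r, seen) {
    for (cidx in which(allowed[r, ])) {
      if (seen[cidx]) next
      seen[cidx] <- TRUE
      res <- if (is.na(match_col[cidx])) list(ok = TRUE, seen = seen)
        else {
          out <- try_row(match_col[cidx], seen)
          list(ok = out$ok, seen = out$seen)
        }
      seen <- res$seen
      if (res$ok) {
        match_col[cidx] <<- r
        return(list(ok = TRUE, seen = seen))
      }
    }
    list(ok = FALSE, seen = seen)
  }
  for (r in seq_len(sz)) {
    res <- try_row(r, rep(FALSE, sz))
    if (!res$ok) return(FALSE)
  }
  TRUE
}

#' Bottleneck distance between barcodes
#'
#' `d_inf = min_theta P(theta)` with the max-form penalty; solved exactly by
#' binary search over the candidate penalty values with a bipartite-matching
#' feasibility test.
#'
#' @inheritParams wasserstein_distance
#' @return the distance.
#' @export
bottleneck_distance <- function(b1, b2, dim = NULL) {
  A <- metric_bars(b1, dim); B <- metric_bars(b2, dim)
  n <- nrow(A); m <- nrow(B)
  if (n == 0 && m == 0) return(0)
  lamA <- if (n) vapply(seq_len(n), function(i) bar_diag(A[i, ]),
                        numeric(1)) else numeric(0)
  lamB <- if (m) vapply(seq_len(m), function(j) bar_diag(B[j, ]),
                        numeric(1)) else numeric(0)
  gm <- gap_matrix(A, B)
  cand <- sort(unique(c(0, as.numeric(gm), lamA, lamB)))
  lo <- 1L; hi <- length(cand)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (bottleneck_feasible(gm, lamA, lamB, cand[mid])) hi <- mid
    else lo <- mid + 1L
  }
  cand[lo]
}

# exhaustive minimum over all partial bijections; test oracle for both
# metrics (feasible for a handful of bars per side)
match_oracle <- function(b1, b2, p = 2, dim = NULL) {
  A <- metric_bars(b1, dim); B <- metric_bars(b2, dim)
  n <- nrow(A); m <- nrow(B)
  best <- Inf
  subsets <- function(v) {
    out <- list(integer(0))
    for (x in v) out <- c(out, lapply(out, function(s) c(s, x)))
    out
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  for (sa in subsets(seq_len(n))) {
    if (length(sa) > m) next
    for (sb in subsets(seq_len(m))) {
      if (length(sb) != length(sa)) next
      for (pb in perms(sb)) {
        theta <- rep(NA_integer_, n)
        theta[sa] <- pb
        pen <- matching_penalty(A, B, theta, p)
        val <- if (is.infinite(p)) pen else pen^(1 / p)
        if (val < best) best <- val
      }
    }
  }
  if (n == 0 && m == 0) 0 else best
}

#' Barcode-space similarity between two molecules
#'
#' Featurizes both molecules into element-specific barcodes over a list of
#' (element combination, filtration scheme, homology dimension) entries and
#' returns the mean Wasserstein `d_2` distance over all entries.  The
#' default entry list is the six barcode sets used with nearest-neighbour
#' regression: dims 0, 1, 2 under the Euclidean and the level-1 multi-level
#' matrices, over the five ligand element combinations
#' CNOS, CNOSPFClBrI, NOH, CNO, CNOSPFClBrIH.
#'
#' @param m1,m2 [molecule()] objects.
#' @param schemes filtration schemes to include.
#' @param dims homology dimensions to include.
#' @param combos element combination strings.
#' @param cap filtration cap in Angstrom.
#' @param p Wasserstein order.
#' @return mean barcode distance (non-negative).
#' @export
molecule_similarity <- function(m1, m2, schemes = c("euclidean",
                                                    "multilevel"),
                                dims = 0:2,
                                combos = topo_combinations("knn5"),
                                cap = 12, p = 2) {
  if (length(schemes) == 0 || length(dims) == 0 || length(combos) == 0)
    stop("empty similarity specification")
  b1 <- knn_barcodes(m1, schemes, combos, cap)
  b2 <- knn_barcodes(m2, schemes, combos, cap)
  total <- 0; k <- 0
  for (key in names(b1)) {
    for (dim in dims) {
      total <- total + wasserstein_distance(b1[[key]], b2[[key]], p, dim)
      k <- k + 1
    }
  }
  total / k
}

# element-specific barcodes for the KNN similarity; one entry per
# (scheme, combination)
knn_barcodes <- function(mol, schemes, combos, cap) {
  stopifnot(inherits(mol, "Molecule"))
  graph <- if ("multilevel" %in% schemes) molecule_bond_graph(mol) else NULL
  out <- list()
  for (scheme in schemes) {
    grp <- list(target = "ligand", complex = "rips", scheme = scheme,
                level = 1, dims = 0:2, cap = cap, id = "knn")
    for (combo in combos) {
      out[[paste(scheme, combo, sep = ":")]] <-
        combo_barcode(mol, grp, combo, graph)
    }
  }
  out
}

#' Pairwise barcode-distance matrix for a set of molecules
#'
#' @param mols list of [molecule()] objects.
#' @param ... passed to [molecule_similarity()].
#' @return symmetric matrix of distances keyed by molecule id.
#' @export
similarity_matrix <- function(mols, ...) {
  n <- length(mols)
  ids <- vapply(seq_along(mols), function(i) {
    id <- mols[[i]]$id
    if (nzchar(id)) id else paste0("mol", i)
  }, character(1))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(d)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- molecule_similarity(mols[[i]], mols[[j]], ...)
    }
  d
}
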