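# Persistence barcodes.  The production path runs through the compiled
# engine (simplex enumeration + Z2 column reduction); the oracles further
# down are independent pure-R implementations used to cross-check it.

#' Construct a barcode
#'
#' @param bars data frame with columns `dim`, `birth`, `death`
#'   (`Inf` marks an OPEN bar, i.e. a class still alive at the cap).
#' @param cap filtration upper limit used.
#' @param complex `"rips"` or `"alpha"`.
#' @param provenance optional list (structure id, selection label, scheme).
#' @return object of class `Barcode`.
#' @export
barcode <- function(bars, cap = Inf, complex = "rips", provenance = list()) {
  if (nrow(bars) == 0)
    bars <- data.frame(dim = integer(), birth = numeric(),
                       death = numeric())
  stopifnot(all(c("dim", "birth", "death") %in% names(bars)))
  if (any(bars$death < bars$birth, na.rm = TRUE))
    stop("bar death before birth")
  structure(list(bars = as.data.frame(bars), cap = cap, complex = complex,
                 provenance = provenance), class = "Barcode")
}

#' @export
print.Barcode <- function(x, ...) {
  tab <- table(factor(x$bars$dim, levels = 0:2))
  cat(sprintf("<Barcode (%s): %d bars [dim0 %d, dim1 %d, dim2 %d], cap=%g>\n",
              x$complex, nrow(x$bars), tab[1], tab[2], tab[3], x$cap))
  invisible(x)
}

empty_barcode <- function(cap = Inf, complex = "rips", provenance = list()) {
  barcode(data.frame(dim = integer(), birth = numeric(), death = numeric()),
          cap, complex, provenance)
}

#' Extract the bars of one homology dimension
#'
#' @param b a [barcode()].
#' @param dim homology dimension.
#' @return data frame of bars.
#' @export
bars_of_dim <- function(b, dim) {
  b$bars[b$bars$dim == dim, , drop = FALSE]
}

#' Cap OPEN bars
#'
#' Replaces infinite deaths by the barcode cap (needed before metric or
#' statistics computations).
#'
#' @param b a [barcode()].
#' @param cap cap to use; defaults to the barcode's own.
#' @return a [barcode()] with finite deaths.
#' @export
cap_bars <- function(b, cap = NULL) {
  if (is.null(cap)) cap <- b$cap
  if (!is.finite(cap)) stop("cannot cap bars with an infinite cap")
  bars <- b$bars
  bars$death <- pmin(bars$death, cap)
  bars <- bars[bars$birth <= cap, , drop = FALSE]
  barcode(bars, cap, b$complex, b$provenance)
}

engine_to_barcode <- function(mat, cap, complex, provenance) {
  bars <- data.frame(dim = as.integer(mat[, 1]), birth = mat[, 2],
                     death = mat[, 3])
  bars <- bars[order(bars$dim, bars$birth, bars$death), , drop = FALSE]
  rownames(bars) <- NULL
  barcode(bars, cap, complex, provenance)
}

#' Vietoris-Rips persistence of a filtration matrix
#'
#' A simplex enters the filtration when all its pairwise values are at most
#' the scale parameter; excluded pairs never form edges.  Classes still alive
#' at the cap are reported as OPEN bars (death `Inf`).
#'
#' @param m a `FiltrationMatrix`.
#' @param max_dim maximum homology dimension (0, 1 or 2).
#' @param cap filtration upper limit; defaults to the matrix axis upper
#'   bound (or `Inf`).
#' @param provenance optional provenance list.
#' @return a [barcode()].
#' @export
rips_persistence <- function(m, max_dim = 2, cap = NULL,
                             provenance = list()) {
  stopifnot(inherits(m, "FiltrationMatrix"))
  if (max_dim > 2) stop("homology dimensions above 2 are unsupported")
  if (is.null(cap)) cap <- m$axis_range[2]
  if (cap < m$axis_range[1]) stop("cap outside the filtration axis range")
  prov <- c(provenance, list(scheme = m$scheme))
  mat <- rips_persistence_cpp(m$values, cap, as.integer(max_dim))
  engine_to_barcode(mat, cap, "rips", prov)
}

#' Alpha-complex persistence of a point cloud
#'
#' Persistence on the radius axis of the alpha filtration: a Delaunay simplex
#' enters once all its edges have length at most twice the radius, so an
#' edge of length L appears at radius L/2.  The Delaunay triangulation is
#' computed by
#' exhaustive circumsphere tests (rank-adaptive: collinear, planar and full
#' 3-D inputs are handled).
#'
#' @param coords numeric matrix of points (rows), 2 or 3 columns.
#' @param max_dim maximum homology dimension (0, 1 or 2).
#' @param cap filtration (radius) upper limit; `Inf` keeps everything.
#' @param provenance optional provenance list.
#' @return a [barcode()].
#' @export
alpha_persistence <- function(coords, max_dim = 2, cap = Inf,
                              provenance = list()) {
  coords <- as.matrix(coords)
  if (ncol(coords) == 2) coords <- cbind(coords, 0)
  if (ncol(coords) != 3) stop("coords must have 2 or 3 columns")
  n <- nrow(coords)
  if (n < 1) stop("need at least one point")
  if (max_dim > 2) stop("homology dimensions above 2 are unsupported")
  if (n == 1) {
    return(barcode(data.frame(dim = 0L, birth = 0, death = Inf),
                   cap, "alpha", provenance))
  }
  dm <- as.matrix(dist(coords))
  if (max(dm) < 1e-9) stop("degenerate input: all points coincide")

  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  sv <- svd(cc, nu = 0)
  rank <- sum(sv$d > 1e-7 * max(sv$d, 1))

  top <- NULL   # matrix of top-dimensional Delaunay simplices (1-based)
  if (rank <= 1) {
    proj <- cc %*% sv$v[, 1, drop = FALSE]
    ord <- order(proj)
    top <- cbind(ord[-n], ord[-1])
  } else if (rank == 2) {
    proj <- cc %*% sv$v[, 1:2, drop = FALSE]
    top <- delaunay2d_cpp(proj, 1e-9)
    if (nrow(top) == 0) top <- cbind(seq_len(n)[-n], seq_len(n)[-1])
  } else {
    top <- delaunay3d_cpp(coords, 1e-9)
    if (nrow(top) == 0) {
      # numerically coplanar despite rank test; retry in the plane
      proj <- cc %*% sv$v[, 1:2, drop = FALSE]
      top <- delaunay2d_cpp(proj, 1e-9)
    }
  }

  # close under faces, assign value = (max edge length) / 2
  seen <- new.env(parent = emptyenv())
  simplices <- vector("list", 0)
  values <- numeric(0)
  add_simplex <- function(v) {
    v <- sort(v)
    key <- paste(v, collapse = ",")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    val <- if (length(v) == 1) 0 else max(dm[v, v]) / 2
    simplices[[length(simplices) + 1L]] <<- as.integer(v - 1L)
    values[length(values) + 1L] <<- val
  }
  for (i in seq_len(n)) add_simplex(i)
  if (!is.null(top) && nrow(top) > 0) {
    for (r in seq_len(nrow(top))) {
      v <- top[r, ]
      k <- length(v)
      for (sz in 2:k) {
        cmb <- combn(k, sz)
        for (ci in seq_len(ncol(cmb))) add_simplex(v[cmb[, ci]])
      }
    }
  }
  keep <- values <= cap
  mat <- reduce_filtration_cpp(simplices[keep], values[keep],
                               as.integer(max_dim))
  engine_to_barcode(mat, cap, "alpha", provenance)
}

# ---- independent oracles -------------------------------------------------

#' Zero-dimensional persistence oracle (Kruskal / union-find)
#'
#' Single-linkage construction: finite entries are processed in ascending
#' order; each merge of two components records a death at the merge value;
#' one OPEN bar remains per final component.  Fully independent of the
#' compiled reduction engine.
#'
#' @param m a `FiltrationMatrix`.
#' @param cap filtration upper limit.
#' @return a [barcode()] with dim-0 bars only.
#' @export
persistence_oracle_0d <- function(m, cap = NULL) {
  stopifnot(inherits(m, "FiltrationMatrix"))
  if (is.null(cap)) cap <- m$axis_range[2]
  n <- m$n
  v <- m$values
  idx <- which(upper.tri(v) & !is.na(v) & v <= cap, arr.ind = TRUE)
  w <- v[cbind(idx[, 1], idx[, 2])]
  ord <- order(w)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  deaths <- numeric(0)
  for (e in ord) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) {
      parent[max(a, b)] <- min(a, b)
      deaths <- c(deaths, w[e])
    }
  }
  k_open <- n - length(deaths)
  bars <- data.frame(dim = 0L,
                     birth = rep(0, length(deaths) + k_open),
                     death = c(sort(deaths), rep(Inf, k_open)))
  barcode(bars, cap, "rips", list(scheme = m$scheme, oracle = "union-find"))
}

#' Boundary-matrix reduction oracle on an explicit filtered complex
#'
#' Standard Z2 column reduction in filtration order, written in plain R:
#' the independent reference for the compiled engine.  Input must be closed
#' under faces with a monotone filtration.
#'
#' @param simplices list of integer vertex vectors (1-based).
#' @param values filtration value per simplex.
#' @param max_dim maximum homology dimension to report.
#' @return a [barcode()].
#' @export
persistence_oracle_reduction <- function(simplices, values, max_dim = 2) {
  m <- length(simplices)
  stopifnot(length(values) == m)
  simplices <- lapply(simplices, function(v) sort(as.integer(v)))
  dims <- vapply(simplices, length, integer(1)) - 1L
  keys <- vapply(simplices, paste, character(1), collapse = ",")
  ord <- order(values, dims, keys)
  simplices <- simplices[ord]; values <- values[ord]; dims <- dims[ord]
  keys <- keys[ord]
  index_of <- setNames(seq_len(m), keys)

  # monotonicity + closure checks
  for (j in seq_len(m)) {
    v <- simplices[[j]]
    if (length(v) > 1) {
      for (drop_i in seq_along(v)) {
        fk <- paste(v[-drop_i], collapse = ",")
        fi <- index_of[fk]
        if (is.na(fi)) stop("complex not closed under faces")
        if (values[fi] > values[j]) stop("non-monotone filtration")
      }
    }
  }

  R <- vector("list", m)
  low_inv <- rep(NA_integer_, m)
  birth_paired <- rep(FALSE, m)
  death_paired <- rep(FALSE, m)
  bars <- list()
  for (j in seq_len(m)) {
    v <- simplices[[j]]
    col <- integer(0)
    if (length(v) > 1)
      col <- sort(unname(vapply(seq_along(v), function(i)
        index_of[[paste(v[-i], collapse = ",")]], integer(1))))
    repeat {
      if (length(col) == 0) break
      piv <- col[length(col)]
      if (is.na(low_inv[piv])) break
      other <- R[[low_inv[piv]]]
      col <- sort(union(setdiff(col, other), setdiff(other, col)))
    }
    R[[j]] <- col
    if (length(col) > 0) {
      piv <- col[length(col)]
      low_inv[piv] <- j
      birth_paired[piv] <- TRUE
      death_paired[j] <- TRUE
      if (dims[piv] <= max_dim && values[j] > values[piv])
        bars[[length(bars) + 1L]] <-
          c(dims[piv], values[piv], values[j])
    }
  }
  for (j in seq_len(m)) {
    if (!birth_paired[j] && !death_paired[j] && dims[j] <= max_dim)
      bars[[length(bars) + 1L]] <- c(dims[j], values[j], Inf)
  }
  bars <- if (length(bars)) do.call(rbind, bars) else
    matrix(numeric(), ncol = 3)
  engine_to_barcode(bars, if (m > 0) max(values) else Inf, "oracle", list())
}

# Full Rips complex (all simplices up to max_dim + 1) of a filtration matrix
# as an explicit simplex list; feeds the reduction oracle in tests.
rips_complex_explicit <- function(m, cap = Inf, max_dim = 2) {
  v <- m$values
  n <- m$n
  simplices <- as.list(seq_len(n))
  values <- rep(0, n)
  top <- min(max_dim + 1, n - 1)
  if (top >= 1) {
    for (k in seq_len(top)) {
      cmb <- combn(n, k + 1)
      for (ci in seq_len(ncol(cmb))) {
        vs <- cmb[, ci]
        sub <- v[vs, vs]
        ww <- sub[upper.tri(sub)]
        if (any(is.na(ww)) || max(ww) > cap) next
        simplices[[length(simplices) + 1L]] <- vs
        values[length(values) + 1L] <- max(ww)
      }
    }
  }
  list(simplices = simplices, values = values)
}

# ---- barcode serialization ----------------------------------------------

#' Write a barcode to TSV
#'
#' Header line `#complex scheme cap`; rows `dim<TAB>birth<TAB>death` with
#' `inf` for OPEN bars.
#'
#' @param b a [barcode()].
#' @param path output path.
#' @export
write_barcode_tsv <- function(b, path) {
  con <- file(path, "w")
  on.exit(close(con))
  scheme <- if (!is.null(b$provenance$scheme)) b$provenance$scheme else "NA"
  writeLines(sprintf("#%s\t%s\t%g", b$complex, scheme, b$cap), con)
  if (nrow(b$bars) > 0) {
    d <- ifelse(is.infinite(b$bars$death), "inf",
                formatC(b$bars$death, format = "g", digits = 10))
    writeLines(sprintf("%d\t%s\t%s", b$bars$dim,
                       formatC(b$bars$birth, format = "g", digits = 10), d),
               con)
  }
  invisible(path)
}

#' Read a barcode from TSV
#'
#' @param path file written by [write_barcode_tsv()].
#' @return a [barcode()].
#' @export
read_barcode_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- lines[-1]
  if (length(body) == 0)
    return(empty_barcode(as.numeric(hdr[3]), hdr[1],
                         list(scheme = hdr[2])))
  parts <- do.call(rbind, strsplit(body, "\t"))
  death <- ifelse(parts[, 3] == "inf", Inf, as.numeric(parts[, 3]))
  barcode(data.frame(dim = as.integer(parts[, 1]),
                     birth = as.numeric(parts[, 2]), death = death),
          as.numeric(hdr[3]), hdr[1], list(scheme = hdr[2]))
}
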