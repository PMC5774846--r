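# Deterministic synthetic-structure generators.  Every generator is a pure
# function of its arguments: the RNG state is saved, seeded and restored
# around each call, so the same spec always yields the same output.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629 + 1)
}

#' Generate a canonical or random point cloud
#'
#' Canonical shapes have oracle-known barcodes: `line` (collinear points at
#' spacing `scale`), `square` (the four corners of a `scale`-sided square),
#' `circle` (`n` points equally spaced on a radius-`scale` circle),
#' `tetrahedron` (regular, edge `scale`) and `random` (uniform in a
#' `scale`-sided cube).
#'
#' @param shape one of `"line"`, `"square"`, `"circle"`, `"tetrahedron"`,
#'   `"random"`.
#' @param n number of points (shapes with fixed vertex counts ignore it).
#' @param scale size parameter in Angstrom.
#' @param seed integer seed (used by `"random"`).
#' @return numeric matrix of 3-D coordinates (rows).
#' @export
make_point_cloud <- function(shape = c("line", "square", "circle",
                                       "tetrahedron", "random"),
                             n = 4, scale = 1, seed = 1) {
  shape <- match.arg(shape)
  if (n < 1) stop("n must be at least 1")
  switch(shape,
    line = cbind(seq_len(n) - 1, 0, 0) * scale,
    square = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0) * scale,
    circle = {
      th <- 2 * pi * (seq_len(n) - 1) / n
      cbind(cos(th), sin(th), 0) * scale
    },
    tetrahedron = {
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      v / sqrt(8) * scale        # edge length = scale
    },
    random = with_seed(seed, matrix(runif(3 * n, 0, scale), ncol = 3)))
}

#' Generate a toy ligand-like molecule
#'
#' A connected bonded tree with bond lengths in 1.3-1.8 Angstrom, elements
#' drawn from the palette, and Gasteiger-like partial charges in
#' \[-0.5, 0.5\] centred so they sum to zero.  Roles are set to ligand.
#'
#' @param n_atoms number of atoms (>= 2).
#' @param element_palette symbols to sample from.
#' @param seed integer seed.
#' @return a [molecule()].
#' @export
make_toy_molecule <- function(n_atoms = 10,
                              element_palette = c("C", "C", "N", "O"),
                              seed = 1) {
  if (n_atoms < 2) stop("n_atoms must be at least 2")
  with_seed(seed, {
    xyz <- matrix(0, n_atoms, 3)
    bonds <- matrix(integer(), ncol = 2)
    for (i in seq(2, n_atoms)) {
      repeat {
        parent <- sample.int(i - 1, 1)
        len <- runif(1, 1.3, 1.8)
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        pos <- xyz[parent, ] + dir * len
        others <- setdiff(seq_len(i - 1), parent)
        ok <- length(others) == 0 ||
          min(sqrt(rowSums((xyz[others, , drop = FALSE] -
                              matrix(pos, length(others), 3,
                                     byrow = TRUE))^2))) > 1.5
        if (ok) break
      }
      xyz[i, ] <- pos
      bonds <- rbind(bonds, c(parent, i))
    }
    elements <- c("C", sample(element_palette, n_atoms - 1,
                              replace = TRUE))
    q <- runif(n_atoms, -0.5, 0.5)
    q <- q - mean(q)
    atoms <- data.frame(serial = seq_len(n_atoms), element = elements,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        charge = q, role = "ligand",
                        stringsAsFactors = FALSE)
    molecule(atoms, bonds, id = sprintf("toy-%d-%d", n_atoms, seed))
  })
}

#' Generate a perturbed conformer
#'
#' Produces a different conformation of the same molecule by rotating the
#' subtree on one side of each bridge bond through a random torsion angle.
#' Bond topology and every bond length are preserved exactly (rotations are
#' about the bond axes); the angles are rescaled until no atom moves more
#' than `magnitude` from its original position.  Molecules whose bond graph
#' has no bridges (or no bonds) are returned unchanged.
#'
#' @param m a [molecule()].
#' @param magnitude maximum per-atom displacement, Angstrom.
#' @param seed integer seed.
#' @return a [molecule()] (new conformer).
#' @export
perturb_conformation <- function(m, magnitude, seed = 1) {
  stopifnot(inherits(m, "Molecule"), magnitude >= 0)
  if (magnitude == 0 || nrow(m$bonds) == 0) return(m)
  n <- n_atoms(m)
  xyz0 <- coords(m)
  adj <- vector("list", n)
  for (i in seq_len(nrow(m$bonds))) {
    a <- m$bonds[i, 1]; b <- m$bonds[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  # component containing `b` after cutting the (a, b) edge
  side_of <- function(a, b) {
    seen <- rep(FALSE, n)
    seen[b] <- TRUE
    queue <- b
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    which(seen)
  }
  rotate_about <- function(p, a, b, theta) {
    ax <- b - a
    ax <- ax / sqrt(sum(ax^2))
    rel <- sweep(p, 2, a)
    cosT <- cos(theta); sinT <- sin(theta)
    para <- (rel %*% ax) %*% t(ax)
    perp <- rel - para
    crossp <- t(apply(rel, 1, function(v)
      c(ax[2] * v[3] - ax[3] * v[2], ax[3] * v[1] - ax[1] * v[3],
        ax[1] * v[2] - ax[2] * v[1])))
    sweep(para + perp * cosT + crossp * sinT, 2, a, `+`)
  }
  with_seed(seed, {
    bridges <- which(vapply(seq_len(nrow(m$bonds)), function(i) {
      a <- m$bonds[i, 1]; b <- m$bonds[i, 2]
      !(a %in% side_of(a, b))     # bridge iff cutting disconnects a from b
    }, logical(1)))
    if (length(bridges) == 0) return(m)
    angles <- runif(length(bridges), -pi / 6, pi / 6)
    repeat {
      xyz <- xyz0
      for (k in seq_along(bridges)) {
        bond <- m$bonds[bridges[k], ]
        side <- side_of(bond[1], bond[2])
        side <- setdiff(side, bond[2])   # the bonded atom sits on the axis
        if (length(side) == 0) next
        xyz[side, ] <- rotate_about(xyz[side, , drop = FALSE],
                                    xyz[bond[1], ], xyz[bond[2], ],
                                    angles[k])
      }
      disp <- sqrt(rowSums((xyz - xyz0)^2))
      if (max(disp) <= magnitude || max(abs(angles)) < 1e-6) break
      angles <- angles * 0.7
    }
    m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
    m$id <- paste0(m$id, "-conf")
    m
  })
}

icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
             c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v / sqrt(1 + phi^2)            # unit radius
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic target/active/decoy screening set
#'
#' Per target, a rigid icosahedral cage of protein-role atoms forms the
#' pocket.  Actives receive complementary contacts: cross-role near-pairs
#' placed at 2.8-3.5 Angstrom with opposite-sign partial charges of
#' magnitude scaled by `effect`.  Decoys receive randomized contacts whose
#' distances are inflated by `effect` and whose contact charges carry
#' random signs.  At `effect = 0` actives and decoys are drawn from the
#' same distribution.
#'
#' @param n_targets number of protein targets.
#' @param n_actives,n_decoys compounds per target.
#' @param effect non-negative effect size separating the classes
#'   (default 1).
#' @param seed integer seed.
#' @param n_ligand_atoms atoms per compound.
#' @param n_contacts contact pairs per compound.
#' @return list with `complexes` (list of [complex_structure()]),
#'   `labels` (`"active"`/`"decoy"`), `targets`, `ids` and the generating
#'   parameters in `spec`.
#' @export
make_screen_set <- function(n_targets = 2, n_actives = 20, n_decoys = 60,
                            effect = 1, seed = 1, n_ligand_atoms = 8,
                            n_contacts = 4) {
  stopifnot(effect >= 0, n_targets >= 1, n_actives >= 1, n_decoys >= 1)
  pocket_radius <- 6
  complexes <- list(); labels <- character(); targets <- character()
  ids <- character()
  for (t in seq_len(n_targets)) {
    tseed <- derive_seed(seed, t)
    pocket <- with_seed(tseed, {
      rot <- random_rotation()
      xyz <- icosahedron_vertices() %*% rot * pocket_radius
      qs <- runif(12, 0.1, 0.5) * sample(c(-1, 1), 12, replace = TRUE)
      atoms <- data.frame(serial = 1:12,
                          element = sample(c("C", "N", "O", "S"), 12,
                                           replace = TRUE),
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          charge = qs, role = "protein",
                          stringsAsFactors = FALSE)
      molecule(atoms, id = sprintf("pocket-%d", t))
    })
    n_cmp <- n_actives + n_decoys
    is_active <- c(rep(TRUE, n_actives), rep(FALSE, n_decoys))
    for (ci in seq_len(n_cmp)) {
      cseed <- derive_seed(tseed, ci + 100)
      lig <- make_toy_molecule(n_ligand_atoms,
                               element_palette = c("C", "C", "N", "O"),
                               seed = cseed)
      lig <- with_seed(derive_seed(cseed, 7), {
        ctr <- colMeans(coords(lig))
        lig$atoms$x <- lig$atoms$x - ctr[1]
        lig$atoms$y <- lig$atoms$y - ctr[2]
        lig$atoms$z <- lig$atoms$z - ctr[3]
        pocket_idx <- sample.int(12, n_contacts)
        atom_idx <- sample.int(n_ligand_atoms, n_contacts)
        m_chg <- 0.4 * min(effect, 1)
        for (k in seq_len(n_contacts)) {
          pv <- as.numeric(coords(pocket)[pocket_idx[k], ])
          d <- runif(1, 2.8, 3.5)
          if (!is_active[ci]) d <- d + effect * runif(1, 0.5, 2)
          pos <- pv * (1 - d / sqrt(sum(pv^2)))
          lig$atoms[atom_idx[k], c("x", "y", "z")] <- as.list(pos)
          sgn <- if (is_active[ci]) -sign(pocket$atoms$charge[pocket_idx[k]])
                 else sample(c(-1, 1), 1)
          lig$atoms$charge[atom_idx[k]] <- sgn * m_chg
        }
        lig
      })
      lig$id <- sprintf("t%d-c%d-%s", t, ci,
                        if (is_active[ci]) "active" else "decoy")
      complexes[[length(complexes) + 1L]] <-
        complex_structure(pocket, lig, id = lig$id)
      labels <- c(labels, if (is_active[ci]) "active" else "decoy")
      targets <- c(targets, sprintf("target%d", t))
      ids <- c(ids, lig$id)
    }
  }
  list(complexes = complexes, labels = labels, targets = targets,
       ids = ids,
       spec = list(n_targets = n_targets, n_actives = n_actives,
                   n_decoys = n_decoys, effect = effect, seed = seed))
}
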