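# Shared random-input generators for the property-style tests.

# random symmetric filtration matrix; a fraction of pairs excluded (NA)
rand_filtration <- function(n, seed, p_exclude = 0.2, scale = 5) {
  set.seed(seed)
  v <- matrix(0, n, n)
  up <- which(upper.tri(v))
  vals <- runif(length(up), 0, scale)
  vals[runif(length(up)) < p_exclude] <- NA
  v[up] <- vals
  v <- v + t(v)
  diag(v) <- 0
  topomol:::new_filtration_matrix(v, "random", c(0, Inf))
}

rand_cloud <- function(n, seed, scale = 3) {
  set.seed(seed)
  matrix(runif(3 * n, 0, scale), ncol = 3)
}

# random barcode with closed bars
rand_barcode <- function(n_bars, seed, cap = 10, dim = 1) {
  set.seed(seed)
  birth <- runif(n_bars, 0, cap * 0.6)
  death <- birth + runif(n_bars, 0, cap * 0.4)
  barcode(data.frame(dim = rep(as.integer(dim), n_bars), birth = birth,
                     death = death), cap = cap)
}

# sorted (dim, birth, death) matrix for bar-multiset comparison
bar_multiset <- function(b, digits = 8) {
  m <- as.matrix(b$bars[, c("dim", "birth", "death")])
  m <- round(m, digits)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

expect_same_bars <- function(b1, b2, tol = 1e-7) {
  m1 <- bar_multiset(b1)
  m2 <- bar_multiset(b2)
  expect_equal(nrow(m1), nrow(m2))
  if (nrow(m1) == nrow(m2)) {
    finite <- is.finite(m1) & is.finite(m2)
    expect_true(all(is.finite(m1) == is.finite(m2)))
    expect_lt(max(abs(m1[finite] - m2[finite]), 0), tol)
  }
}

atoms_at <- function(xyz, element = "C", role = "ligand", charge = NA_real_) {
  xyz <- matrix(xyz, ncol = 3)
  data.frame(element = rep_len(element, nrow(xyz)), x = xyz[, 1],
             y = xyz[, 2], z = xyz[, 3],
             charge = rep_len(charge, nrow(xyz)),
             role = rep_len(role, nrow(xyz)), stringsAsFactors = FALSE)
}

minimal_pdb_text <- function() {
  c(paste0("ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
           "  1.00  0.00           C"),
    paste0("ATOM      2  N   ALA A   1       1.500   0.000   0.000",
           "  1.00  0.00           N"),
    "END")
}

minimal_mol2_text <- function() {
  c("@<TRIPOS>MOLECULE", "test", "    3     2", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "      1 C1    0.0000    0.0000    0.0000 C.3   1 LIG  -0.1000",
    "      2 O1    1.4000    0.0000    0.0000 O.3   1 LIG  -0.3000",
    "      3 N1    2.8000    0.0000    0.0000 N.ar  1 LIG   0.4000",
    "@<TRIPOS>BOND",
    "     1    1    2 1",
    "     2    2    3 1")
}
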