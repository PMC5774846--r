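test_that("Rips persistence reproduces hand-derived barcodes", {
  collinear <- euclidean_matrix(atoms_at(rbind(c(0, 0, 0), c(1, 0, 0),
                                               c(3, 0, 0))))
  b <- rips_persistence(collinear, 0, cap = Inf)
  expect_same_bars(b, barcode(data.frame(dim = 0L, birth = 0,
                                         death = c(1, 2, Inf))))

  sq <- euclidean_matrix(atoms_at(make_point_cloud("square")))
  b1 <- rips_persistence(sq, 1, cap = Inf)
  d1 <- bars_of_dim(b1, 1)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$birth, 1)
  expect_equal(d1$death, sqrt(2))

  chain <- molecule(atoms_at(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
                    rbind(c(1, 2), c(2, 3)))
  m1 <- multilevel_matrix(chain, build_bond_graph(chain), 1)
  bm <- rips_persistence(m1, 0, cap = 12)
  expect_same_bars(bm, barcode(data.frame(dim = 0L, birth = 0,
                                          death = c(2, Inf, Inf))))
  expect_error(rips_persistence(sq, 3), "unsupported")
})

test_that("the union-find oracle matches its closed-form cases", {
  collinear <- euclidean_matrix(atoms_at(rbind(c(0, 0, 0), c(1, 0, 0),
                                               c(3, 0, 0))))
  expect_same_bars(persistence_oracle_0d(collinear, cap = Inf),
                   rips_persistence(collinear, 0, cap = Inf))

  excl <- rand_filtration(5, seed = 1, p_exclude = 1)
  b <- persistence_oracle_0d(excl, cap = Inf)
  expect_equal(nrow(b$bars), 5)
  expect_true(all(is.infinite(b$bars$death)))

  single <- euclidean_matrix(atoms_at(c(0, 0, 0)))
  expect_equal(persistence_oracle_0d(single, cap = Inf)$bars$death, Inf)
})

test_that("the reduction oracle handles explicit complexes", {
  # triangle boundary: three vertices, three edges at value 1, no 2-simplex
  simp <- c(as.list(1:3), list(c(1, 2), c(1, 3), c(2, 3)))
  vals <- c(0, 0, 0, 1, 1, 1)
  b <- persistence_oracle_reduction(simp, vals)
  d1 <- bars_of_dim(b, 1)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$birth, 1)
  expect_true(is.infinite(d1$death))

  # filled triangle: the 2-simplex at sqrt(2) kills the loop
  simp2 <- c(simp, list(c(1, 2, 3)))
  vals2 <- c(vals, sqrt(2))
  b2 <- persistence_oracle_reduction(simp2, vals2)
  d12 <- bars_of_dim(b2, 1)
  expect_equal(d12$birth, 1)
  expect_equal(d12$death, sqrt(2))

  b3 <- persistence_oracle_reduction(list(1), 0)
  expect_same_bars(b3, barcode(data.frame(dim = 0L, birth = 0,
                                          death = Inf)))
  expect_error(persistence_oracle_reduction(list(1, 2, c(1, 2)),
                                            c(0, 0.5, 0.2)),
               "non-monotone")
  expect_error(persistence_oracle_reduction(list(1, c(1, 2)), c(0, 1)),
               "closed under faces")
})

test_that("Rips dim-0 equals the union-find oracle on random matrices", {
  for (seed in 1:30) {
    n <- 3 + (seed %% 13)
    m <- rand_filtration(n, seed, p_exclude = 0.3)
    expect_same_bars(rips_persistence(m, 0, cap = Inf),
                     persistence_oracle_0d(m, cap = Inf))
  }
})

test_that("Rips all-dims equals the reduction oracle on random clouds", {
  for (seed in 1:20) {
    n <- 4 + (seed %% 4)
    m <- euclidean_matrix(atoms_at(rand_cloud(n, seed)))
    engine <- rips_persistence(m, 2, cap = Inf)
    cx <- topomol:::rips_complex_explicit(m, cap = Inf, max_dim = 2)
    oracle <- persistence_oracle_reduction(cx$simplices, cx$values, 2)
    expect_same_bars(engine, oracle)
  }
})

test_that("scaling coordinates scales every finite birth and death", {
  xyz <- rand_cloud(8, seed = 31)
  b1 <- rips_persistence(euclidean_matrix(atoms_at(xyz)), 2, cap = Inf)
  b2 <- rips_persistence(euclidean_matrix(atoms_at(xyz * 2.5)), 2,
                         cap = Inf)
  m1 <- bar_multiset(b1); m2 <- bar_multiset(b2)
  expect_equal(nrow(m1), nrow(m2))
  fin <- is.finite(m1[, 3])
  expect_equal(m2[, 2], m1[, 2] * 2.5, tolerance = 1e-7)
  expect_equal(m2[fin, 3], m1[fin, 3] * 2.5, tolerance = 1e-7)
})

test_that("a connected matrix leaves exactly one OPEN dim-0 bar", {
  for (seed in 1:5) {
    m <- euclidean_matrix(atoms_at(rand_cloud(7, seed)))
    b <- rips_persistence(m, 2, cap = Inf)
    open0 <- sum(b$bars$dim == 0 & is.infinite(b$bars$death))
    expect_equal(open0, 1)
  }
})

test_that("alpha persistence follows the half-edge-length radius rule", {
  b <- alpha_persistence(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_same_bars(b, barcode(data.frame(dim = 0L, birth = 0,
                                         death = c(1, Inf))))
  tet <- make_point_cloud("tetrahedron", scale = 2)
  bt <- alpha_persistence(tet, 2)
  d0 <- bars_of_dim(bt, 0)
  expect_equal(sort(d0$death), c(1, 1, 1, Inf))
  expect_error(alpha_persistence(matrix(0, 3, 3)), "coincide")
})

test_that("alpha dim-0 deaths are half the Euclidean-Rips dim-0 deaths", {
  for (seed in 1:8) {
    xyz <- rand_cloud(5 + seed, seed + 100)
    da <- bars_of_dim(alpha_persistence(xyz, 0), 0)$death
    dr <- bars_of_dim(rips_persistence(euclidean_matrix(atoms_at(xyz)),
                                       0, cap = Inf), 0)$death
    expect_equal(sort(da[is.finite(da)]) * 2, sort(dr[is.finite(dr)]),
                 tolerance = 1e-8)
  }
})

test_that("barcodes round-trip through the TSV dialect", {
  b <- rips_persistence(euclidean_matrix(atoms_at(rand_cloud(6, 9))), 2,
                        cap = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_barcode_tsv(b, f)
  back <- read_barcode_tsv(f)
  expect_same_bars(b, back)
  expect_equal(back$cap, b$cap)
  expect_equal(back$complex, b$complex)
})
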