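test_that("euclidean matrices hold pairwise distances", {
  two <- atoms_at(rbind(c(0, 0, 0), c(3, 0, 0)))
  m <- euclidean_matrix(two)
  expect_equal(m$values[1, 2], 3)
  expect_equal(euclidean_matrix(atoms_at(c(1, 2, 3)))$values,
               matrix(0, 1, 1))
  tri <- atoms_at(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)))
  mt <- euclidean_matrix(tri)
  expect_equal(unique(round(mt$values[upper.tri(mt$values)], 10)), 2)
})

test_that("multi-level matrices exclude pairs within n bond hops", {
  chain <- molecule(atoms_at(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
                    rbind(c(1, 2), c(2, 3)))
  g <- build_bond_graph(chain)
  m1 <- multilevel_matrix(chain, g, 1)
  expect_true(is.na(m1$values[1, 2]))           # bonded pair excluded
  expect_true(is.na(m1$values[2, 3]))
  expect_equal(m1$values[1, 3], 2)              # only A-C finite
  m2 <- multilevel_matrix(chain, g, 2)
  expect_true(all(is.na(m2$values[upper.tri(m2$values)])))
  expect_error(multilevel_matrix(chain, g, 0), "level")

  # level n+1 exclusions are a superset of level n
  mol <- make_toy_molecule(12, seed = 4)
  gg <- build_bond_graph(mol)
  for (lev in 1:3) {
    a <- is.na(multilevel_matrix(mol, gg, lev)$values)
    b <- is.na(multilevel_matrix(mol, gg, lev + 1)$values)
    expect_true(all(b[a]))
  }
})

test_that("interactive matrices keep exactly the cross-partition entries", {
  at <- atoms_at(rbind(c(0, 0, 0), c(3, 0, 0)))
  m <- interactive_matrix(euclidean_matrix(at), c("A1", "A2"))
  expect_equal(m$values[1, 2], 3)

  at4 <- atoms_at(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(1, 2, 0)))
  m4 <- interactive_matrix(euclidean_matrix(at4),
                           c("A1", "A1", "A2", "A2"))
  off <- m4$values[upper.tri(m4$values)]
  expect_equal(sum(!is.na(off)), 4)             # |A1| * |A2|
  expect_error(interactive_matrix(euclidean_matrix(at4),
                                  rep("A1", 4)), "two")

  # composes with the electrostatic matrix: cross pairs carry Phi values
  atq <- atoms_at(rbind(c(0, 0, 0), c(4, 0, 0)), charge = c(0.4, -0.4))
  me <- interactive_matrix(electrostatic_matrix(atq, c = 100),
                           c("A1", "A2"))
  expect_equal(me$values[1, 2], 1 / (1 + exp(4)), tolerance = 1e-12)
})

test_that("correlation matrices map geometry onto [0, 1]", {
  at <- atoms_at(rbind(c(0, 0, 0), c(0, 0, 0), c(2, 0, 0)))
  k <- kernel_spec("lorentz", eta = 2, nu = 2)
  m <- correlation_matrix(at[c(1, 3), ], k)
  expect_equal(m$values[1, 2], 0.5)             # d = eta, nu = 2
  m0 <- correlation_matrix(at[c(1, 2), ], k)
  expect_equal(m0$values[1, 2], 0)              # d = 0 -> Phi = 1

  ats <- atoms_at(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)),
                  element = c("C", "S", "C"))
  ms <- correlation_matrix(ats, k, exclude = ats$element == "S")
  expect_true(all(is.na(ms$values[2, -2])))
  expect_false(is.na(ms$values[1, 3]))

  # values within [0, 1]; Lorentz Phi strictly decreasing in d
  rnd <- atoms_at(matrix(runif(30, 0, 8), ncol = 3))
  mr <- correlation_matrix(rnd, k)
  off <- mr$values[upper.tri(mr$values)]
  expect_true(all(off >= 0 & off <= 1))
  d <- seq(0.1, 10, by = 0.1)
  expect_true(all(diff(topomol:::lorentz_phi(d, 2, 2)) < 0))
})

test_that("electrostatic values follow the charge-product sigmoid", {
  expect_equal(electrostatic_value(3, 0, 0.4, 100), 0.5)
  expect_equal(electrostatic_value(4, 0.4, -0.4, 100), 1 / (1 + exp(4)))
  expect_equal(electrostatic_value(4, 0.4, 0.4, 100), 1 / (1 + exp(-4)))
  expect_error(electrostatic_value(0, 0.1, 0.1, 100), "positive")

  # strictly monotone in q_i q_j / d, bounded in (0, 1)
  qq_d <- seq(-0.2, 0.2, by = 0.01)
  vals <- vapply(qq_d, function(z) electrostatic_value(1, z, 1, 100),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))

  atq <- atoms_at(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)),
                  charge = 0)
  m <- electrostatic_matrix(atq)
  expect_true(all(m$values[upper.tri(m$values)] == 0.5))
  atna <- atoms_at(rbind(c(0, 0, 0), c(4, 0, 0)), charge = c(0.1, NA))
  expect_error(electrostatic_matrix(atna), "charge")
})

test_that("rigidity index sums the Lorentz kernel over neighbours", {
  k <- kernel_spec("lorentz", eta = 2, nu = 2)
  expect_equal(rigidity_index(atoms_at(c(0, 0, 0)), k), 0)
  pair <- atoms_at(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(rigidity_index(pair, k), c(0.5, 0.5))
  tri <- atoms_at(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)))
  expect_equal(rigidity_index(tri, k), rep(1, 3))
})

test_that("charge density is a screened sum over atoms", {
  one <- atoms_at(c(1, 1, 1), charge = 1)
  expect_equal(charge_density(one, c(1, 1, 1), eta = 2), 1)
  expect_equal(charge_density(one, c(1, 1, 1 + 20), eta = 2), exp(-10))
  two <- atoms_at(rbind(c(-1, 0, 0), c(1, 0, 0)), charge = c(1, -1))
  expect_equal(charge_density(two, c(0, 0, 0), eta = 1), 0)
})

test_that("every filtration matrix is symmetric with a zero diagonal", {
  mol <- make_toy_molecule(9, seed = 7)
  g <- build_bond_graph(mol)
  mats <- list(euclidean_matrix(mol), multilevel_matrix(mol, g, 1),
               electrostatic_matrix(mol), correlation_matrix(mol))
  for (m in mats) {
    expect_equal(diag(m$values), rep(0, m$n))
    expect_true(isTRUE(all.equal(m$values, t(m$values))))
  }
})

test_that("filtration matrices round-trip through the INF-sentinel TSV", {
  mol <- make_toy_molecule(6, seed = 2)
  m <- multilevel_matrix(mol, build_bond_graph(mol), 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_filtration_tsv(m, f)
  back <- read_filtration_tsv(f)
  expect_equal(back$scheme, m$scheme)
  expect_equal(is.na(back$values), is.na(m$values))
  expect_equal(back$values, m$values, tolerance = 1e-8)
})
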