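test_that("PDB and Mol2 files parse into molecules with the right records", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_text(), pdb)
  mol <- read_structure(pdb, "pdb")
  expect_equal(n_atoms(mol), 2)
  expect_equal(nrow(mol$bonds), 0)
  expect_equal(mol$atoms$element, c("C", "N"))

  m2 <- withr::local_tempfile(fileext = ".mol2")
  writeLines(minimal_mol2_text(), m2)
  mol2 <- read_structure(m2, "mol2")
  expect_equal(n_atoms(mol2), 3)
  expect_equal(nrow(mol2$bonds), 2)
  expect_equal(mol2$atoms$charge, c(-0.1, -0.3, 0.4))
  expect_equal(mol2$atoms$element, c("C", "O", "N"))

  expect_error(read_structure(file.path(tempdir(), "no-such-file.mol2")),
               "cannot read")
  bad <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>ATOM", "1 C1 nope nope nope C.3"), bad)
  expect_error(read_structure(bad, "mol2"), "parse error")
})

test_that("generated Mol2/PDB files round-trip through the readers", {
  mol <- make_toy_molecule(8, seed = 42)
  f <- withr::local_tempfile(fileext = ".mol2")
  write_mol2(mol, f)
  back <- read_structure(f)
  expect_equal(n_atoms(back), 8)
  expect_equal(nrow(back$bonds), nrow(mol$bonds))
  expect_equal(back$atoms$element, mol$atoms$element)
  expect_equal(back$atoms$charge, mol$atoms$charge, tolerance = 1e-3)
  expect_equal(coords(back), coords(mol), tolerance = 1e-3,
               ignore_attr = TRUE)

  ss <- make_screen_set(1, 1, 1, seed = 3)
  pock <- ss$complexes[[1]]$protein
  fp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(pock, fp)
  backp <- read_structure(fp, "pdb")
  expect_equal(n_atoms(backp), 12)
  expect_equal(coords(backp), coords(pock), tolerance = 1e-2,
               ignore_attr = TRUE)
})

test_that("bond graphs give BFS hop distances and perceive bonds by radii", {
  chain <- molecule(atoms_at(rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0))),
                    rbind(c(1, 2), c(2, 3)))
  g <- build_bond_graph(chain)
  expect_equal(g$D[1, 3], 2)
  expect_equal(g$D[1, 1], 0)

  apart <- molecule(atoms_at(rbind(c(0, 0, 0), c(9, 0, 0))))
  g2 <- build_bond_graph(apart, "distance_cutoff")
  expect_true(is.infinite(g2$D[1, 2]))

  cc <- molecule(atoms_at(rbind(c(0, 0, 0), c(1.4, 0, 0))))
  g3 <- build_bond_graph(cc, "distance_cutoff")
  expect_equal(g3$D[1, 2], 1)   # 1.4 <= 1.3 * (0.76 + 0.76)

  expect_error(build_bond_graph(molecule(atoms_at(matrix(numeric(),
                                                         ncol = 3)))),
               "empty")
})

test_that("hop distances agree with a Floyd-Warshall oracle on random graphs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:20, 1)
    nb <- sample.int(2 * n, 1)
    bonds <- unique(t(replicate(nb, sort(sample.int(n, 2)))))
    mol <- molecule(atoms_at(matrix(rnorm(3 * n), ncol = 3)), bonds)
    D <- build_bond_graph(mol)$D
    # Floyd-Warshall oracle
    O <- matrix(Inf, n, n); diag(O) <- 0
    for (i in seq_len(nrow(bonds))) O[bonds[i, 1], bonds[i, 2]] <-
      O[bonds[i, 2], bonds[i, 1]] <- 1
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
      if (O[i, k] + O[k, j] < O[i, j]) O[i, j] <- O[i, k] + O[k, j]
    expect_equal(D, O)
    expect_true(all(D == t(D)))
  }
})

test_that("element selections match roles, stay idempotent and monotone", {
  ch4 <- molecule(atoms_at(rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0),
                                 c(0, 1, 0), c(0, -1, 0)),
                           element = c("C", "H", "H", "H", "H")))
  expect_equal(nrow(select_atoms(ch4, element_selection(ligand = "C"))), 1)
  expect_equal(nrow(select_atoms(ch4, element_selection(ligand = "N"))), 0)
  expect_equal(nrow(select_atoms(ch4, element_selection(ligand = "heavy"))),
               1)

  prot <- molecule(atoms_at(matrix(rnorm(12), ncol = 3), element = "C",
                            role = "protein"))
  lig <- molecule(atoms_at(rbind(c(0, 0, 5), c(1, 0, 5)), element = "O"))
  cx <- complex_structure(prot, lig)
  both <- select_atoms(cx, element_selection(protein = "C", ligand = "O"))
  expect_equal(nrow(both), 6)
  expect_equal(both$role, c(rep("protein", 4), rep("ligand", 2)))

  mol <- make_toy_molecule(12, element_palette = c("C", "N", "O", "S"),
                           seed = 9)
  small <- select_atoms(mol, element_selection(ligand = "CN"))
  large <- select_atoms(mol, element_selection(ligand = "CNOS"))
  expect_true(all(small$serial %in% large$serial))     # monotone
  again <- select_atoms(mol, element_selection(ligand = "CN"))
  expect_identical(small, again)                       # idempotent
})

test_that("binding-site truncation keeps protein atoms within the cutoff", {
  prot <- molecule(atoms_at(rbind(c(5, 0, 0), c(20, 0, 0)),
                            role = "protein"))
  lig <- molecule(atoms_at(c(0, 0, 0)))
  cx <- complex_structure(prot, lig)
  tr <- truncate_binding_site(cx, 12)
  expect_equal(n_atoms(tr$protein), 1)
  expect_equal(n_atoms(tr$ligand), 1)

  tr_all <- truncate_binding_site(cx, 100)
  expect_equal(n_atoms(tr_all$protein), 2)

  expect_warning(tr_none <- truncate_binding_site(cx, 1), "removed every")
  expect_equal(n_atoms(tr_none$protein), 0)

  counts <- vapply(c(30, 12, 6, 1), function(cutoff)
    n_atoms(suppressWarnings(truncate_binding_site(cx, cutoff))$protein),
    numeric(1))
  expect_true(all(diff(counts) <= 0))   # non-increasing with cutoff
})
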