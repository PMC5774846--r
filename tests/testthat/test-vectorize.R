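test_that("counts in bins follow the birth/death/overlap rules", {
  b <- barcode(data.frame(dim = 1L, birth = c(0, 0), death = c(1, 3)),
               cap = 4)
  bins <- bin_spec(c(0, 2), c(2, 4))
  cc <- counts_in_bins(b, bins, 1)
  expect_equal(cc$births, c(2, 0))
  expect_equal(cc$deaths, c(1, 1))
  expect_equal(cc$persistences, c(2, 1))

  cc0 <- counts_in_bins(empty_barcode(4), bins, 0)
  expect_equal(unlist(cc0), rep(0, 6), ignore_attr = TRUE)

  # interactive distance-bin list, deaths at 2.7 and 5.0
  bi <- barcode(data.frame(dim = 0L, birth = 0, death = c(2.7, 5.0)),
                cap = 12)
  int_bins <- bin_spec(c(0, 2.5, 3, 3.5, 4.5, 6),
                       c(2.5, 3, 3.5, 4.5, 6, 12))
  expect_equal(counts_in_bins(bi, int_bins, 0)$deaths,
               c(0, 1, 0, 0, 1, 0))

  # OPEN bars: no death bin, but overlap every bin right of birth
  bo <- barcode(data.frame(dim = 0L, birth = 0, death = Inf), cap = 12)
  co <- counts_in_bins(bo, int_bins, 0)
  expect_equal(sum(co$deaths), 0)
  expect_equal(co$persistences, rep(1, 6))
})

test_that("summed birth counts over a bin cover equal the bar count", {
  for (seed in 1:5) {
    b <- rand_barcode(12, seed, cap = 10)
    bins <- uniform_bins(0, 10, 20)
    cc <- counts_in_bins(b, bins, 1)
    expect_equal(sum(cc$births), sum(b$bars$birth <= 10))
  }
})

test_that("barcode statistics match direct computation", {
  b <- barcode(data.frame(dim = 1L, birth = c(0, 0), death = c(1, 3)),
               cap = 5)
  s <- barcode_statistics(b, 1)
  expect_equal(unname(s[1:6]), c(0, 0, 0, 0, 0, 2))        # Birth block
  expect_equal(unname(s[13:20]), c(2, 1, 3, 1, 4, 2, 0, 3)) # Persistence

  one <- barcode(data.frame(dim = 1L, birth = 2, death = 5), cap = 6)
  s1 <- barcode_statistics(one, 1)
  expect_equal(unname(s1[c("pers.longest.birth", "pers.longest.death")]),
               c(2, 5))

  s0 <- barcode_statistics(empty_barcode(5), 1)
  expect_equal(unname(s0), rep(0, 20))
  expect_equal(length(barcode_statistics(empty_barcode(5), 0)), 6)
})

test_that("slice statistics partition bars then summarize the complement", {
  b <- barcode(data.frame(dim = 1L, birth = c(0, 2), death = c(1, 3)),
               cap = 4)
  bins <- bin_spec(c(0, 2), c(2, 4))
  s <- slice_statistics(b, "death", bins, 1)
  expect_equal(unname(s["slice1.birth.avg"]), 0)
  expect_equal(unname(s["slice2.birth.avg"]), 2)
  expect_equal(unname(s["slice1.birth.cnt"]), 1)

  # all bars in one slice -> other slice blocks are zero
  ball <- barcode(data.frame(dim = 1L, birth = c(0, 0.5),
                             death = c(1, 1.5)), cap = 4)
  sall <- slice_statistics(ball, "death", bins, 1)
  expect_equal(unname(sall["slice2.birth.cnt"]), 0)
  expect_equal(unname(sall["slice2.birth.avg"]), 0)

  sp <- slice_statistics(b, "persistence", bins, 1)
  expect_equal(length(sp), 2 * 12)   # birth + death stats per slice
})

test_that("2-D images stack the eight count channels per combination", {
  ss <- make_screen_set(1, 1, 1, seed = 5)
  cx <- ss$complexes[[1]]
  bins <- uniform_bins(0, 12, 120)
  img <- complex_2d_image(cx, bins)
  expect_equal(dim(img), c(120, 128, 16))

  # channel sums equal the corresponding counts totals per combination
  combos <- topo_combinations("image128")
  lab <- combos$label[1]
  sel <- element_selection(protein = combos$protein[1],
                           ligand = combos$ligand[1])
  at <- select_atoms(cx, sel)
  b <- alpha_persistence(as.matrix(at[, c("x", "y", "z")]), 2, 12)
  cc <- counts_in_bins(b, bins, 0)
  expect_equal(sum(img[, 1, 1]), sum(cc$deaths))
  expect_equal(sum(img[, 1, 2]), sum(cc$persistences))

  # single-structure mode: 8 channels; empty barcodes -> zero tensor
  bc <- list(A = empty_barcode(12), B = empty_barcode(12))
  img8 <- build_2d_image(bc, bins)
  expect_equal(dim(img8), c(120, 2, 8))
  expect_true(all(img8 == 0))
  expect_error(build_2d_image(bc, bins, ordering = c("A", "B", "C")),
               "missing combination")
})

test_that("feature order is invariant under bar permutations", {
  b <- rand_barcode(10, 3, cap = 8)
  set.seed(4)
  bp <- barcode(b$bars[sample.int(10), ], cap = 8)
  bins <- uniform_bins(0, 8, 10)
  expect_equal(counts_in_bins(b, bins, 1), counts_in_bins(bp, bins, 1))
  expect_equal(barcode_statistics(b, 1), barcode_statistics(bp, 1))
  expect_equal(slice_statistics(b, "death", bins, 1),
               slice_statistics(bp, "death", bins, 1))
})

test_that("feature-group schemas are fixed by the config, not the input", {
  mol1 <- make_toy_molecule(6, seed = 1)
  mol2 <- make_toy_molecule(14, element_palette = c("C", "N", "O", "S"),
                            seed = 2)
  f1 <- assemble_features(mol1, "A-B012-E-S")
  f2 <- assemble_features(mol2, "A-B012-E-S")
  expect_equal(length(f1$values), 1472)   # 46 stats x 32 combinations
  expect_identical(f1$schema, f2$schema)

  ss <- make_screen_set(1, 1, 1, seed = 2)
  cx <- ss$complexes[[1]]
  expect_equal(length(assemble_features(cx, "R-B0-I-C")$values), 960)
  fa <- assemble_features(cx, "A-B12-E-S")
  expect_equal(length(fa$values), 80)
  expect_true(all(grepl("^(heavy|C)\\.", fa$schema)))
  expect_error(assemble_features(mol1, "no-such-group"), "unknown")
})
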