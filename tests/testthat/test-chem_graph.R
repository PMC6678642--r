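test_that("ring perception counts rings of each size per atom", {
  acyclic <- compute_ring_membership(mol_propane())
  expect_true(all(acyclic$ring_counts == 0L))
  expect_false(any(acyclic$aromatic))

  cp <- compute_ring_membership(mol_cyclopropane())
  expect_equal(unname(cp$ring_counts[, "ring3"]), rep(1L, 3))
  expect_true(all(cp$ring_counts[, -1] == 0L))

  bz <- compute_ring_membership(mol_benzene())
  expect_equal(unname(bz$ring_counts[, "ring6"]), rep(1L, 6))
  expect_true(all(bz$aromatic))
})

test_that("SSSR matches ChemmineR's exhaustive ring search on fused systems", {
  # naphthalene-like fused 6-6 skeleton (SSSR = two 6-rings, not the 10-ring)
  ang <- 2 * pi * (0:5) / 6
  hexA <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  mol <- molecule("naph", rep("C", 10),
                  rbind(hexA, hexA[1:4, ] + matrix(c(2.42, 1.4, 0), 4, 3,
                                                   byrow = TRUE)),
                  data.frame(i = c(1, 2, 3, 4, 5, 6, 1, 7, 8, 9, 2),
                             j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 10),
                             order = 1))
  per <- perceive_rings(mol)
  expect_length(per$rings, 2L)
  expect_setequal(lengths(per$rings), c(6L, 6L))

  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(mol), tmp)
  sdf <- ChemmineR::read.SDFset(tmp)
  ref <- ChemmineR::rings(sdf[[1]], upper = 10, type = "all")
  ref_sets <- lapply(ref, function(r) sort(as.integer(sub("^.*_", "", r))))
  ours <- lapply(per$rings, sort)
  for (ring in ours)
    expect_true(any(vapply(ref_sets, identical, logical(1), y = ring)))
})

test_that("atom features follow the 33-wide schema with an exact one-hot", {
  expect_identical(atom_feature_width(), 33L)
  af <- featurize_atoms(mol_propane())
  expect_equal(dim(af), c(3, 33))
  expect_equal(unname(rowSums(af[, 1:23])), rep(1, 3))      # one-hot block
  expect_equal(unname(af[, "type_C"]), rep(1, 3))
  expect_equal(unname(af[1, c("vdw", "covalent")]), c(1.70, 0.76))
  expect_true(all(af[, paste0("ring", 3:8)] == 0))
  expect_equal(unname(af[, "charge"]), rep(0, 3))

  # unknown element lands in the trailing "other" slot
  uuo <- molecule("x", "Uuo", rbind(c(0, 0, 0)))
  afu <- featurize_atoms(uuo)
  expect_equal(unname(afu[1, 23]), 1)
  expect_equal(sum(afu[1, 1:23]), 1)
})

test_that("neighbor rule: bonded union within-cutoff, capped, symmetric", {
  # bonded pair well inside the cutoff
  close_pair <- molecule("p", c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                         data.frame(i = 1, j = 2, order = 1))
  expect_equal(determine_neighbors(close_pair, 4), list(2L, 1L))

  # far apart, not bonded -> not neighbors
  far <- molecule("f", c("C", "C"), rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(determine_neighbors(far, 4), list(integer(), integer()))

  # bonded but strained beyond the cutoff -> the bond still wins
  strained <- molecule("s", c("C", "C"), rbind(c(0, 0, 0), c(5.2, 0, 0)),
                       data.frame(i = 1, j = 2, order = 1))
  expect_equal(determine_neighbors(strained, 4), list(2L, 1L))

  # cap: central atom sees at most max_neighbors, nearest first,
  # and the relation stays symmetric
  n <- 16
  coords <- rbind(c(0, 0, 0), cbind(seq(0.5, 3.5, length.out = n - 1), 0, 0))
  star <- molecule("star", rep("C", n), coords)
  nb <- determine_neighbors(star, distance_cutoff = 4, max_neighbors = 5)
  expect_lte(length(nb[[1]]), n - 1)
  for (a in seq_len(n)) for (b in nb[[a]]) expect_true(a %in% nb[[b]])

  # single atom: no neighbors
  expect_equal(determine_neighbors(mol_helium(), 4), list(integer()))
})

test_that("pair features encode bond type, distance and shared ring", {
  mol <- molecule("cc", c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)),
                  data.frame(i = 1, j = 2, order = 1))
  expect_equal(unname(featurize_pair(1, 2, mol)), c(1, 0, 0, 1.54, 0))
  expect_identical(pair_feature_width(), 5L)

  # non-bonded neighbor pair -> None bit
  nf <- featurize_pair(1, 3, mol_propane())
  expect_equal(unname(nf[1:3]), c(0, 0, 1))

  # symmetry and same-ring flag on a ring
  cp <- mol_cyclopropane()
  expect_equal(featurize_pair(1, 2, cp), featurize_pair(2, 1, cp))
  expect_equal(unname(featurize_pair(1, 2, cp)[["same_ring"]]), 1)

  # aromatic ring: Kekule assignment uses only Single/Double bits
  bz <- mol_benzene(kekule = FALSE)
  pf <- featurize_pair(1, 2, bz)
  expect_equal(sum(pf[1:3]), 1)
  expect_equal(unname(pf[["none"]]), 0)

  expect_error(featurize_pair(2, 2, mol_propane()))
})

test_that("build_graph assembles a consistent symmetric graph", {
  g <- build_graph(mol_methane())
  expect_equal(dim(g$atom_features), c(5, 33))
  # all atoms within 4 A: complete neighbor graph on 5 atoms
  expect_equal(length(g$edges$center), 20L)
  ij <- paste(g$edges$center, g$edges$nbr)
  ji <- paste(g$edges$nbr, g$edges$center)
  expect_setequal(ij, ji)
  expect_true(all(g$edges$center != g$edges$nbr))
  # C-H bonded pairs carry the Single bit
  ch <- g$edges$center == 1L
  expect_equal(unname(g$edges$pair[ch, 1]), rep(1, 4))

  he <- build_graph(mol_helium())
  expect_equal(dim(he$atom_features), c(1, 33))
  expect_length(he$edges$center, 0L)

  expect_error(molecule("empty", character(), matrix(0, 0, 3)))
})

test_that("atom relabeling yields an isomorphic graph", {
  mols <- fixture_mols(5, seed = 31, size_range = c(5L, 10L))
  set.seed(99)
  for (mol in mols) {
    g1 <- build_graph(mol)
    perm <- sample(length(mol$elements))
    g2 <- build_graph(permute_molecule(mol, perm))
    sorted_rows <- function(m) m[do.call(order, as.data.frame(m)), ]
    expect_equal(sorted_rows(g1$atom_features), sorted_rows(g2$atom_features),
                 ignore_attr = TRUE)
    pr1 <- cbind(g1$edges$pair)
    pr2 <- cbind(g2$edges$pair)
    expect_equal(sorted_rows(pr1), sorted_rows(pr2), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("feature one-hots sum to one on randomized molecules", {
  for (mol in fixture_mols(8, seed = 77)) {
    g <- build_graph(mol)
    expect_equal(unname(rowSums(g$atom_features[, 1:23, drop = FALSE])),
                 rep(1, g$n_atoms))
    if (length(g$edges$center))
      expect_equal(unname(rowSums(g$edges$pair[, 1:3, drop = FALSE])),
                   rep(1, length(g$edges$center)))
    expect_true(all(g$edges$pair[, 4] > 0))
  }
})

test_that("graph JSON dump round-trips the feature matrices", {
  g <- build_graph(mol_propane())
  tmp <- withr::local_tempfile(fileext = ".json")
  write_graph_json(g, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$n_atoms, 3L)
  expect_equal(dim(back$atom_features), dim(g$atom_features))
})
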