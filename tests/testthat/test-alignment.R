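# Common substructures and rigid-body superposition.

test_that("identical molecules yield themselves as the MCS", {
  mols <- with_toy_coords(lapply(1:3, function(k)
    parse_smiles("Cc1ccccc1", paste0("tol", k))))
  mcs <- cluster_mcs(mols)
  expect_equal(mcs$natoms, 7)
  expect_length(match_smarts(mcs$smarts, mols[[1]]), 2)  # mirror symmetry
  expect_equal(mcs$source, "mcs")
})

test_that("small-pair MCS respects min_atoms and the no-common case", {
  pair <- with_toy_coords(list(parse_smiles("CC", "e"),
                               parse_smiles("CCO", "eo")))
  m2 <- cluster_mcs(pair, min_atoms = 2)
  expect_equal(m2$natoms, 2)
  expect_equal(m2$smarts, "C-C")
  expect_null(cluster_mcs(pair, min_atoms = 3))
  disjoint <- with_toy_coords(list(parse_smiles("C", "m"),
                                   parse_smiles("O", "w")))
  expect_null(cluster_mcs(disjoint))
  expect_error(cluster_mcs(list(parse_smiles("CC"), parse_smiles("CC"))),
               "3D coordinates")
})

test_that("cluster MCS is order-invariant and matches the exhaustive oracle", {
  sets <- list(
    c("CCO", "CC(C)O", "OCCN"),
    c("CCCC", "CC(C)C", "CCC"),
    c("CC(=O)O", "CC(=O)N", "CC=O"),
    c("NCCO", "NCCS", "NCC", "NCCCC"))
  for (si in seq_along(sets)) {
    mols <- with_toy_coords(lapply(seq_along(sets[[si]]), function(k)
      parse_smiles(sets[[si]][k], paste0("m", k))))
    base <- cluster_mcs(mols, min_atoms = 1)
    expect_false(is.null(base))
    expect_equal(base$natoms, oracle_mcs_size(mols),
                 info = paste("set", si))
    # SMARTS re-matches every member (self-consistency)
    for (m in mols)
      expect_gt(length(match_smarts(base$smarts, m, max_matches = 1L)), 0)
    # order invariance of the achieved size
    set.seed(si)
    perm <- sample(length(mols))
    permuted <- cluster_mcs(mols[perm], min_atoms = 1)
    expect_equal(permuted$natoms, base$natoms, info = paste("set", si))
  }
})

test_that("MSF selection picks the largest covering fragment", {
  frags <- list(
    fragment_feature("Br", incidence = c(1L, 1L, 1L)),
    fragment_feature("Br-c:c:c-O", incidence = c(1L, 1L, 1L)),
    fragment_feature("C-C-O", incidence = c(1L, 0L, 1L)))
  sub <- msf_select(1:3, frags)
  expect_equal(sub$smarts, "Br-c:c:c-O")
  expect_equal(sub$source, "fragment")
  # fragment not covering all members is ignored even if larger
  expect_equal(msf_select(c(1, 2), frags)$smarts, "Br-c:c:c-O")
  expect_null(msf_select(1:3, list(fragment_feature("N",
                                                    incidence = c(1L, 0L, 1L)))))
  expect_error(msf_select(1:3, list()), "structural features")
  # deterministic lexicographic tie-break at equal size
  tie <- list(fragment_feature("C-C-O", incidence = c(1L, 1L)),
              fragment_feature("C-C-N", incidence = c(1L, 1L)))
  expect_equal(msf_select(1:2, tie)$smarts, "C-C-N")
})

test_that("a known rigid motion is inverted to machine precision", {
  mol <- with_toy_coords(list(parse_smiles("Cc1ccccc1O", "ref")))[[1]]
  sub <- cluster_mcs(list(mol, mol))
  moved <- mol
  moved$coords <- mol$coords %*% t(rotation_z(pi / 6)) +
    matrix(c(1, -2, 3), nrow(mol$coords), 3, byrow = TRUE)
  tr <- align_to_reference(mol, moved, sub)
  expect_lt(tr$rmsd, 1e-9)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(apply_transform(tr, moved$coords) - mol$coords)), 1e-9)
  # exact copy: identity
  tr0 <- align_to_reference(mol, mol, sub)
  expect_lt(tr0$rmsd, 1e-12)
  expect_equal(tr0$rotation, diag(3), tolerance = 1e-9)
})

test_that("reflections are never used even for mirror images", {
  mol <- with_toy_coords(list(parse_smiles("NC(C)C(=O)O", "ala")))[[1]]
  sub <- cluster_mcs(list(mol, mol), min_atoms = 3)
  mirrored <- mol
  mirrored$coords <- mol$coords %*% diag(c(-1, 1, 1))
  tr <- align_to_reference(mol, mirrored, sub)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  expect_gt(tr$rmsd, 1e-6)  # a proper rotation cannot undo a reflection
})

test_that("superposition RMSD matches independent references", {
  set.seed(14)
  for (rep in 1:5) {
    P <- matrix(rnorm(18), 6, 3)
    Q <- matrix(rnorm(18), 6, 3)
    # distinct elements -> a single unambiguous substructure embedding
    els <- c("C", "N", "O", "S", "F", "Br")
    atoms <- data.frame(element = els, charge = 0L, aromatic = FALSE)
    bonds <- data.frame(i = 1:5, j = 2:6, order = 1L, aromatic = FALSE)
    ref <- molecule_graph(atoms, bonds, coords = Q, id = "q")
    mov <- molecule_graph(atoms, bonds, coords = P, id = "p")
    sub <- common_substructure("C-N-O-S-F-Br", 6, "mcs")
    tr <- align_to_reference(ref, mov, sub)
    # closed-form quaternion solution (machine precision)
    expect_equal(tr$rmsd, oracle_superposition_rmsd(P, Q),
                 tolerance = 1e-9)
    # bio3d's fitted RMSD (rounded to 3 decimals by bio3d)
    expect_equal(tr$rmsd, bio3d::rmsd(as.vector(t(Q)), as.vector(t(P)),
                                      fit = TRUE),
                 tolerance = 1e-3)
  }
})

test_that("cluster alignment fixes the first member and helps the rest", {
  base <- with_toy_coords(list(parse_smiles("Oc1ccc(Br)cc1", "b1")))[[1]]
  members <- list(base)
  set.seed(23)
  for (k in 2:4) {
    m <- base
    m$id <- paste0("b", k)
    m$coords <- base$coords %*% t(rotation_z(runif(1, 0.3, 2))) +
      matrix(rnorm(3, sd = 2), nrow(base$coords), 3, byrow = TRUE)
    members[[k]] <- m
  }
  sub <- cluster_mcs(members)
  trs <- align_cluster(members, sub)
  expect_equal(trs[[1]]$rotation, diag(3))
  expect_equal(trs[[1]]$translation, c(0, 0, 0))
  for (k in 2:4) {
    expect_lt(trs[[k]]$rmsd, 1e-9)
    before <- sqrt(mean(rowSums((members[[k]]$coords - base$coords)^2)))
    after_coords <- apply_transform(trs[[k]], members[[k]]$coords)
    after <- sqrt(mean(rowSums((after_coords - base$coords)^2)))
    expect_lt(after, before)
  }
  # singleton cluster: single identity transform
  single <- align_cluster(members[1], sub)
  expect_length(single, 1)
  expect_equal(single[[1]]$rmsd, 0)
})

test_that("under 3 matched atoms alignment degrades to translation", {
  atoms <- data.frame(element = c("C", "O"), charge = 0L, aromatic = FALSE)
  bonds <- data.frame(i = 1, j = 2, order = 1L, aromatic = FALSE)
  ref <- molecule_graph(atoms, bonds, coords = rbind(c(0, 0, 0), c(1.4, 0, 0)),
                        id = "r")
  mov <- molecule_graph(atoms, bonds, coords = rbind(c(5, 5, 5), c(6.4, 5, 5)),
                        id = "m")
  sub <- common_substructure("C-O", 2, "mcs")
  expect_warning(tr <- align_to_reference(ref, mov, sub), "translation-only")
  expect_equal(tr$rotation, diag(3))
  expect_lt(tr$rmsd, 1e-9)
})
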