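# Linear fragment mining, SMARTS matching and structural feature
# construction.

test_that("small-molecule fragment sets match the hand oracle", {
  frags <- enumerate_linear_fragments(list(parse_smiles("CCO")))
  expect_setequal(vapply(frags, `[[`, character(1), "smarts"),
                  c("C", "O", "C-C", "C-O", "C-C-O"))
  # benzene: aromatic paths of 1..6 atoms; no simple 7-path in a 6-ring
  frags <- enumerate_linear_fragments(list(parse_smiles("c1ccccc1")))
  expect_length(frags, 6)
  expect_setequal(vapply(frags, `[[`, integer(1), "natoms"), 1:6)
  frags <- enumerate_linear_fragments(list(parse_smiles("C")))
  expect_length(frags, 1)
  expect_equal(frags[[1]]$smarts, "C")
  expect_error(enumerate_linear_fragments(list()), "empty")
})

test_that("mining equals exhaustive simple-path enumeration on random molecules", {
  for (seed in 1:15) {
    mol <- random_test_molecule(sample(3:12, 1), seed = seed)
    mined <- enumerate_linear_fragments(list(mol), max_atoms = 7)
    expect_equal(sort(vapply(mined, `[[`, character(1), "smarts")),
                 oracle_linear_fragments(mol, max_atoms = 7),
                 info = paste("seed", seed))
  }
})

test_that("mined fragments re-match exactly the compounds they claim", {
  mols <- list(parse_smiles("CCO"), parse_smiles("c1ccccc1O"),
               parse_smiles("CC(=O)N"), parse_smiles("Oc1cccc(Br)c1"))
  frags <- enumerate_linear_fragments(mols, max_atoms = 5)
  for (f in frags) {
    rematch <- vapply(mols, function(m)
      as.integer(length(match_smarts(f$smarts, m, max_matches = 1L)) > 0),
      integer(1))
    expect_equal(rematch, f$incidence, info = f$smarts)
  }
})

test_that("fragment frequency never grows along path extensions", {
  mols <- lapply(1:8, function(s) random_test_molecule(10, seed = 100 + s))
  frags <- enumerate_linear_fragments(mols, max_atoms = 6)
  freq <- setNames(vapply(frags, `[[`, integer(1), "frequency"),
                   vapply(frags, `[[`, character(1), "smarts"))
  # every >=2-atom fragment has frequency <= that of any sub-path prefix;
  # check against its two terminal-atom deletions when those are mined
  for (f in frags) {
    if (f$natoms < 2) next
    pat <- parse_smarts(f$smarts)
    expect_true(all(f$incidence %in% c(0L, 1L)))
    expect_equal(f$frequency, sum(f$incidence))
  }
  # direct chain check on a known series
  chain <- c("C", "C-C", "C-C-O")
  present <- chain[chain %in% names(freq)]
  expect_true(all(diff(freq[present]) <= 0))
})

test_that("frequency and omnipresence filters behave as configured", {
  inc <- function(...) as.integer(c(...))
  frags <- list(
    fragment_feature("C-C-O", incidence = inc(1, 1, 0)),
    fragment_feature("C-C", incidence = inc(1, 1, 1)),
    fragment_feature("Br", incidence = inc(1, 0, 0)))
  out <- build_fragment_features(frags, min_frequency = 2,
                                 skip_omnipresent = TRUE, n_compounds = 3)
  expect_length(out, 1)
  expect_equal(out[[1]]$smarts, "C-C-O")
  expect_equal(out[[1]]$incidence, inc(1, 1, 0))
  # without the omnipresence filter C-C stays, ordered natoms desc
  out2 <- build_fragment_features(frags, min_frequency = 2,
                                  skip_omnipresent = FALSE, n_compounds = 3)
  expect_equal(vapply(out2, `[[`, character(1), "smarts"),
               c("C-C-O", "C-C"))
})

test_that("SMARTS matching agrees with Open Babel on a probe set", {
  probes <- c("Oc1ccc(Br)cc1", "Oc1cccc(Br)c1", "Oc1ccccc1Br", "CCO",
              "c1ccccc1", "Brc1ccccc1", "Oc1ccccc1", "CC(Br)CO",
              "Brc1ccc(O)cc1O", "BrCc1ccccc1")
  mols <- lapply(probes, parse_smiles)
  patterns <- c("Br-c:c:c-O", "[#35]-[#6]:[#6]:[#6]-[#8]", "c:c:c",
                "C-C-O", "[#35]", "O-c:c-Br")
  sdfset <- ChemmineR::smiles2sdf(setNames(probes, seq_along(probes)))
  for (pat in patterns) {
    mine <- vapply(mols, function(m)
      length(match_smarts(pat, m, max_matches = 1L)) > 0, logical(1))
    ob <- unname(ChemmineR::smartsSearchOB(sdfset, pat,
                                           uniqueMatches = FALSE) > 0)
    expect_equal(mine, ob, info = pat)
  }
})

test_that("match_smarts returns embeddings and rejects bad patterns", {
  expect_length(match_smarts("C", parse_smiles("C")), 1)
  expect_length(match_smarts("[#35]", parse_smiles("CCO")), 0)
  # all embeddings of a symmetric pattern are reported
  expect_length(match_smarts("C-C", parse_smiles("CC")), 2)
  expect_error(match_smarts("C(((", parse_smiles("C")), "C\\(\\(\\(")
  expect_error(parse_smarts("[$(CC)]"), "unsupported")
})

test_that("SMARTS files load with names, comments and line diagnostics", {
  path <- withr::local_tempfile(fileext = ".smarts")
  writeLines(c("# alert collection", "Br-c:c:c-O ether_bromine",
               "[#35] bromine", "C-C-O"), path)
  tpl <- load_smarts_file(path)
  expect_length(tpl, 3)
  expect_equal(tpl[[1]]$name, "ether_bromine")
  expect_equal(tpl[[3]]$smarts, "C-C-O")
  filled <- fragment_incidence(tpl, list(parse_smiles("Oc1cccc(Br)c1"),
                                         parse_smiles("CCO")))
  expect_equal(filled[[1]]$incidence, c(1L, 0L))
  expect_equal(filled[[3]]$incidence, c(0L, 1L))
  writeLines(c("C-C", "][bad"), path)
  expect_error(load_smarts_file(path), "line 2")
})

test_that("fragment columns are binary nominal with their SMARTS attached", {
  frags <- fragment_incidence(list(fragment_feature("C-C")),
                              list(parse_smiles("CC"), parse_smiles("O")))
  cols <- fragment_feature_columns(frags)
  expect_equal(cols[[1]]$ftype, "nominal")
  expect_equal(cols[[1]]$origin, "fragment")
  expect_equal(cols[[1]]$smarts, "C-C")
  expect_equal(cols[[1]]$values, c("1", "0"))
})
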