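# Reading and writing datasets: SDF round-trips, SMILES lists, CSV
# joins, feature typing.

write_two_record_sdf <- function(path) {
  # hand-written 2-record SDF: ethanol (with logD tag) and methanol
  # (without), both with flat coordinates
  lines <- c(
    "ethanol", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.2000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0", "M  END",
    ">  <logD>", "1.25", "", "$$$$",
    "methanol", "  test", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.4000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "M  END", "$$$$")
  writeLines(lines, path)
  path
}

test_that("SDF parsing keeps molecules, tags and missing tag values", {
  path <- write_two_record_sdf(withr::local_tempfile(fileext = ".sdf"))
  ds <- read_dataset(path)
  expect_length(ds$molecules, 2)
  expect_equal(compound_ids(ds), c("ethanol", "methanol"))
  expect_equal(nrow(ds$molecules[[1]]$atoms), 3)
  expect_equal(nrow(ds$molecules[[2]]$bonds), 1)
  expect_named(ds$features, "logD")
  expect_equal(ds$features$logD$origin, "dataset")
  # tag missing on record 2 -> explicit missing, column retained
  expect_equal(ds$features$logD$values, c(1.25, NA))
  expect_false(ds$has3d)  # flat z: 2D input accepted
})

test_that("SMILES files parse with whitespace-separated ids", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO eth", "c1ccccc1 benz"), path)
  ds <- read_dataset(path)
  expect_equal(compound_ids(ds), c("eth", "benz"))
  expect_equal(nrow(ds$molecules[[2]]$atoms), 6)
  expect_true(all(ds$molecules[[2]]$atoms$aromatic))
})

test_that("unparseable records are collected; read fails only at zero", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO eth", "C(C junk", "CC ok"), path)
  expect_warning(ds <- read_dataset(path), "line 2")
  expect_length(ds$molecules, 2)
  writeLines(c("((("), path)
  expect_error(read_dataset(path), "no molecule parsed")
})

test_that("CSV join matches on compound id and errors on mismatch", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO eth", "CC eta"), smi)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,act", "eta,0.5", "eth,0.25"), csv)
  ds <- read_dataset(smi, csv = csv)
  expect_equal(ds$features$act$values, c(0.25, 0.5))  # reordered by id
  writeLines(c("id,act", "other,1"), csv)
  expect_error(read_dataset(smi, csv = csv), "eth")
})

test_that("feature types are guessed per the 0/1 ambiguity rule", {
  expect_equal(guess_feature_type(c("1.2", "3.4", "-0.5")), "numeric")
  expect_equal(guess_feature_type(c("active", "inactive",
                                    "moderately-active")), "nominal")
  expect_equal(guess_feature_type(c("0", "1", "0")), "ambiguous")
  # ambiguous defaults to nominal in the column constructor
  fc <- feature_column("f", c("0", "1", "0"))
  expect_equal(fc$ftype, "nominal")
  expect_equal(fc$type_guess, "ambiguous")
  expect_error(guess_feature_type(c(NA, "", "NA")), "all-missing")
  # missing markers never become 0
  fc2 <- feature_column("g", c("1.5", "", "NA"), ftype = "numeric")
  expect_equal(fc2$values, c(1.5, NA, NA))
})

test_that("duplicate compound ids are suffixed with a warning", {
  expect_warning(
    ds <- ches_dataset(list(parse_smiles("C", "x"), parse_smiles("O", "x"))),
    "duplicate")
  expect_equal(compound_ids(ds), c("x", "x_1"))
})

test_that("read-export-read is idempotent on structure and tags", {
  path <- write_two_record_sdf(withr::local_tempfile(fileext = ".sdf"))
  ds <- read_dataset(path)
  out1 <- withr::local_tempfile(fileext = ".sdf")
  export_sdf(ds, scene = NULL, path = out1)
  ds2 <- read_dataset(out1)
  out2 <- withr::local_tempfile(fileext = ".sdf")
  export_sdf(ds2, scene = NULL, path = out2)
  ds3 <- read_dataset(out2)
  for (k in seq_along(ds$molecules)) {
    expect_equal(nrow(ds3$molecules[[k]]$atoms),
                 nrow(ds$molecules[[k]]$atoms))
    expect_equal(nrow(ds3$molecules[[k]]$bonds),
                 nrow(ds$molecules[[k]]$bonds))
  }
  expect_equal(ds3$features$logD$values, ds$features$logD$values)
  # the exported file is valid for an independent SDF parser
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(out1))
  expect_true(all(ChemmineR::validSDF(sdfset)))
})

test_that("scene export honours keep and drops missing-value tags", {
  ds <- generate_structures(
    ches_dataset(list(parse_smiles("CCO", "a"), parse_smiles("CCN", "b"),
                      parse_smiles("CCC", "c")),
                 list(feature_column("y", c(1, NA, 3), ftype = "numeric"))))
  emb <- random_embed(3, seed = 1)
  cl <- no_clustering(3)
  scn <- build_scene(emb, cl, ids = compound_ids(ds))
  path <- withr::local_tempfile(fileext = ".sdf")
  export_sdf(ds, scn, path = path, keep = c(1, 2))
  back <- read_dataset(path)
  expect_length(back$molecules, 2)
  expect_true("cluster" %in% names(back$features))
  # molecule b has missing y -> tag omitted for that record only (the
  # lone surviving value "1" re-reads as an ambiguous 0/1 nominal)
  expect_equal(back$features$y$values, c("1", NA))
  expect_error(export_sdf(ds, scn, path = path, keep = integer(0)),
               "nothing to export")
})

test_that("feature column lengths are enforced against molecule count", {
  expect_error(
    ches_dataset(list(parse_smiles("C", "a")),
                 list(feature_column("f", c(1, 2), ftype = "numeric"))),
    "2 values for 1 molecules")
})
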