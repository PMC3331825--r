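# Scene assembly: superimposition, colors, representatives, histograms,
# view filtering, JSON round-trip.

make_scene <- function(n = 6, k = 2, seed = 1) {
  emb <- random_embed(n, seed = seed)
  labels <- rep(seq_len(k), length.out = n)
  cl <- structure(list(labels = labels, k = k, algorithm = "fixture",
                       params = list(), quality_by_k = NULL, seed = seed),
                  class = "cluster_result")
  build_scene(emb, cl, ids = letters[seq_len(n)])
}

test_that("superimposition moves members to centroids and toggles back", {
  scn <- make_scene(4, 2)
  orig <- scn$positions
  sup <- superimpose(scn)
  for (cl in unique(sup$cluster_of)) {
    idx <- which(sup$cluster_of == cl)
    ctr <- colMeans(orig[idx, , drop = FALSE])
    for (i in idx) expect_equal(unname(sup$positions[i, ]), unname(ctr))
  }
  expect_true(sup$superimposed)
  # centroid multiset is preserved exactly
  back <- superimpose(sup)
  expect_identical(back$positions, orig)
  expect_false(back$superimposed)
  # singleton cluster stays put
  scn1 <- make_scene(3, 3)
  sup1 <- superimpose(scn1)
  expect_equal(sup1$positions, scn1$positions)
})

test_that("numeric highlighting follows the blue-white-red ramp", {
  v <- c(0, 5, 10)
  cols <- value_to_color(v)
  expect_equal(unname(cols[1, ]), c(0L, 0L, 255L))      # min -> blue
  expect_equal(unname(cols[2, ]), c(255L, 255L, 255L))  # midpoint -> white
  expect_equal(unname(cols[3, ]), c(255L, 0L, 0L))      # max -> red
  # missing -> neutral gray; constant -> white
  expect_equal(unname(value_to_color(v, NA)[1, ]), c(128L, 128L, 128L))
  expect_true(all(value_to_color(c(2, 2, 2)) == 255L))
})

test_that("the color gradient is monotone in the value", {
  vals <- seq(-3, 7, length.out = 41)
  cols <- value_to_color(vals)
  expect_true(all(diff(cols[, "r"]) >= 0))
  expect_true(all(diff(cols[, "b"]) <= 0))
})

test_that("nominal colors are distinct, deterministic and cycle", {
  m1 <- nominal_colors(c("active", "inactive", "active"))
  expect_length(m1, 2)
  expect_false(m1[["active"]] == m1[["inactive"]])
  expect_identical(m1, nominal_colors(c("active", "inactive", "active")))
  m3 <- nominal_colors(c("a", "b", "c"))
  expect_equal(length(unique(m3)), 3)
  expect_warning(nominal_colors(as.character(1:30)), "cycling")
})

test_that("representatives follow the maximum/median/minimum modes", {
  members <- c(4L, 7L, 9L)
  values <- rep(NA_real_, 10)
  values[members] <- c(1, 5, 9)
  expect_equal(as.integer(select_representative(members, values, "maximum")), 9L)
  expect_equal(as.integer(select_representative(members, values, "median")), 7L)
  expect_equal(as.integer(select_representative(members, values, "minimum")), 4L)
  # ordering attribute: descending for maximum, ascending otherwise
  expect_equal(attr(select_representative(members, values, "maximum"),
                    "ordering"), c(9L, 7L, 4L))
  expect_equal(attr(select_representative(members, values, "minimum"),
                    "ordering"), c(4L, 7L, 9L))
  # even count: lower median
  values2 <- rep(NA_real_, 10); values2[c(2L, 3L)] <- c(9, 1)
  expect_equal(as.integer(select_representative(c(2L, 3L), values2, "median")),
               3L)
  expect_warning(
    r <- select_representative(members, rep(NA_real_, 10), "maximum"),
    "missing")
  expect_equal(as.integer(r), 4L)
})

test_that("histograms bin left-closed with a closed rightmost bin", {
  h <- feature_histogram(c(0, 0.5, 1), 2)
  expect_equal(h$lower, c(0, 0.5))
  expect_equal(h$upper, c(0.5, 1))
  expect_equal(h$count, c(1L, 2L))  # 0.5 falls in [0.5, 1]
  # counts conserve the number of non-missing values
  set.seed(2)
  v <- c(rnorm(50), NA, NA)
  expect_equal(sum(feature_histogram(v, 7)$count), 50)
  # degenerate constant column: one bin holding everything
  hd <- feature_histogram(c(3, 3, 3), 5)
  expect_equal(nrow(hd), 1)
  expect_equal(hd$count, 3L)
})

test_that("scene removal is a view filter that spares the dataset", {
  ds <- generate_structures(ches_dataset(
    lapply(1:4, function(k) parse_smiles("CCO", paste0("m", k)))))
  snapshot <- ds
  scn <- make_scene(4, 2)
  filtered <- scene_remove(scn, which(scn$cluster_of == 2))
  expect_equal(length(filtered$kept), sum(scn$cluster_of != 2))
  expect_identical(ds, snapshot)  # untouched
  expect_error(scene_remove(scn, 1:4), "every compound")
  # remove -> export -> re-read equals kept count
  path <- withr::local_tempfile(fileext = ".sdf")
  export_sdf(ds, filtered, path = path)
  expect_length(read_dataset(path)$molecules, length(filtered$kept))
})

test_that("scene JSON round-trips byte-identically", {
  scn <- make_scene(5, 2)
  scn <- scene_highlight(scn, "activity",
                         feature_column("activity", c(1, 2, 3, 4, 5),
                                        ftype = "numeric"))
  js <- scene_to_json(scn)
  parsed <- scene_from_json(js)
  js2 <- jsonlite::toJSON(parsed, auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  expect_identical(as.character(js), as.character(js2))
  expect_equal(length(parsed$compounds), 5)
  expect_equal(parsed$compounds[[1]]$id, "a")
})
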