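# Feature preprocessing and the clustering algorithms.

test_that("numeric columns are z-scored with population scaling", {
  M <- preprocess_features(list(feature_column("a", c(1, 2, 3),
                                               ftype = "numeric")))
  expect_equal(as.numeric(M$X), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(M$scaling$a$type, "zscore")
})

test_that("nominal columns one-hot encode completely, with recorded scale", {
  M <- preprocess_features(list(feature_column("b", c("0", "1", "0", "1"),
                                               ftype = "nominal")))
  expect_equal(ncol(M$X), 2)
  s <- M$scaling$b$scale
  expect_true(s > 0)
  # dummies are 0/1 times the block scale: rows sum to the scale factor
  expect_equal(unname(rowSums(M$X)), rep(s, 4))
  expect_setequal(unique(as.numeric(M$X)), c(0, s))
})

test_that("missing values impute by median/mode and never by zero", {
  M <- preprocess_features(list(
    feature_column("num", c(10, NA, 20, 30), ftype = "numeric"),
    feature_column("nom", c("x", "x", NA, "y"), ftype = "nominal")))
  # median of (10,20,30) = 20 -> imputed value z-scores identically to 20
  expect_equal(M$X[2, 1], M$X[3, 1])
  # mode "x" -> row 3 equals rows 1-2 in the one-hot block
  expect_equal(M$X[3, -1], M$X[1, -1])
})

test_that("zero-variance columns drop with warning; all-constant errors", {
  expect_warning(
    M <- preprocess_features(list(
      feature_column("const", c(5, 5, 5), ftype = "numeric"),
      feature_column("ok", c(1, 2, 3), ftype = "numeric"))),
    "zero-variance")
  expect_equal(ncol(M$X), 1)
  expect_error(
    suppressWarnings(preprocess_features(list(
      feature_column("const", c(5, 5, 5), ftype = "numeric")))),
    "no informative features")
})

test_that("k-means recovers separated blobs and honours edge cases", {
  g <- generate_gaussian_features(2, 10, 2, sigma = 0.1, separation = 10,
                                  seed = 5)
  res <- kmeans_cluster(g$M, 2, restarts = 5, seed = 9)
  expect_equal(oracle_ari(res$labels, g$labels), 1)
  expect_equal(kmeans_cluster(g$M, 1, seed = 1)$labels, rep(1L, 20))
  # k = n with distinct points: singletons, WSS 0
  X <- matrix(c(0, 1, 5, 9), 4, 1)
  res_n <- kmeans_cluster(X, 4, restarts = 3, seed = 2)
  expect_equal(sort(res_n$labels), 1:4)
  expect_equal(res_n$params$wss, 0)
  expect_error(kmeans_cluster(X, 5, seed = 1), "between 1 and")
})

test_that("k-means is deterministic given its seed", {
  g <- generate_gaussian_features(3, 8, 3, sigma = 0.5, separation = 4,
                                  seed = 11)
  a <- kmeans_cluster(g$M, 3, restarts = 4, seed = 7)
  b <- kmeans_cluster(g$M, 3, restarts = 4, seed = 7)
  expect_identical(a$labels, b$labels)
})

test_that("Calinski-Harabasz matches the textbook formula", {
  set.seed(31)
  X <- matrix(rnorm(20), 10, 2)
  for (k in 2:4) {
    labels <- sample(k, 10, replace = TRUE)
    labels[seq_len(k)] <- seq_len(k)  # every cluster non-empty
    expect_equal(calinski_harabasz(X, labels),
                 oracle_calinski_harabasz(X, labels), tolerance = 1e-9)
  }
  # degenerate perfect split -> +Inf sentinel
  X0 <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  expect_equal(calinski_harabasz(X0, c(1, 1, 2, 2)), Inf)
  expect_error(calinski_harabasz(X, rep(1, 10)), "undefined")
})

test_that("correct labelings of separated blobs outscore random ones", {
  g <- generate_gaussian_features(2, 10, 2, sigma = 0.1, separation = 10,
                                  seed = 3)
  set.seed(4)
  random_labels <- sample(2, 20, replace = TRUE)
  random_labels[1:2] <- 1:2
  expect_gt(calinski_harabasz(g$M, g$labels),
            calinski_harabasz(g$M, random_labels))
})

test_that("cascade k-means selects the generative k and reports scores", {
  g <- generate_gaussian_features(3, 15, 4, sigma = 0.1, separation = 10,
                                  seed = 21)
  res <- cascade_kmeans(g$M, 2, 5, restarts = 10, seed = 13)
  expect_equal(res$k, 3)
  expect_named(res$quality_by_k, as.character(2:5))
  expect_equal(unname(which.max(res$quality_by_k)), 2)  # k = 3 entry
  expect_equal(oracle_ari(res$labels, g$labels), 1)
  # single blob: a k is still returned with its (weak) scores visible
  g1 <- generate_gaussian_features(1, 12, 3, sigma = 1, separation = 1,
                                   seed = 2)
  res1 <- cascade_kmeans(g1$M, 2, 4, restarts = 3, seed = 1)
  expect_true(res1$k %in% 2:4)
  expect_length(res1$quality_by_k, 3)
})

test_that("cascade clamps k_max to n - 1 with a warning", {
  g <- generate_gaussian_features(2, 3, 2, sigma = 0.2, separation = 5,
                                  seed = 8)
  expect_warning(res <- cascade_kmeans(g$M, 2, 10, restarts = 2, seed = 1),
                 "clamped")
  expect_lte(res$k, 5)
})

test_that("hierarchical clustering agrees with hand agglomeration", {
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  res <- hierarchical_cluster(X, "complete", k = 2)
  expect_equal(oracle_ari(res$labels, c(1, 1, 2, 2)), 1)
  expect_equal(hierarchical_cluster(X, "average", k = 4)$k, 4)
  expect_equal(hierarchical_cluster(X, "single", k = 1)$labels, rep(1L, 4))
  expect_error(hierarchical_cluster(X, "centroidal", k = 2),
               "invalid linkage")
})

test_that("farthest-first puts the outlier in its own cluster", {
  X <- matrix(c(0, 1, 2, 100), 4, 1)
  for (seed in 1:5) {
    res <- farthest_first(X, 2, seed = seed)
    expect_equal(oracle_ari(res$labels, c(1, 1, 1, 2)), 1,
                 info = paste("seed", seed))
  }
  expect_equal(farthest_first(X, 1, seed = 1)$k, 1)
  expect_equal(farthest_first(X, 4, seed = 1)$k, 4)
})

test_that("no_clustering yields one all-member cluster marked 'none'", {
  res <- no_clustering(5)
  expect_equal(res$labels, rep(1L, 5))
  expect_equal(res$k, 1)
  expect_equal(res$algorithm, "none")
  expect_equal(no_clustering(1)$labels, 1L)
})

test_that("own k-means matches stats::kmeans on the objective", {
  g <- generate_gaussian_features(3, 10, 3, sigma = 0.4, separation = 6,
                                  seed = 17)
  ours <- kmeans_cluster(g$M, 3, restarts = 10, seed = 5)
  set.seed(5)
  ref <- stats::kmeans(g$M$X, centers = 3, nstart = 10, iter.max = 100)
  expect_equal(ours$params$wss, ref$tot.withinss, tolerance = 1e-6)
})
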