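# Feature preprocessing and compound partitioning. The cascade k-means +
# Calinski-Harabasz selection is the workhorse; hierarchical clustering
# goes through stats::hclust, farthest-first traversal and Lloyd k-means
# are implemented here (restarts chosen by within-cluster sum of squares,
# empty clusters re-seeded at the farthest point, deterministic under
# seed). Distances are Euclidean throughout.

#' Preprocess feature columns into a numeric matrix
#'
#' Numeric columns are median-imputed and z-scored (population standard
#' deviation); zero-variance columns
#' are dropped with a warning. Nominal columns are mode-imputed and
#' one-hot encoded (0/1 dummies, one per level), then the whole block is
#' multiplied by `1/sqrt(sum of dummy variances)` so each original
#' feature contributes total variance 1, comparable to a z-scored numeric
#' column. The per-column centring/scaling is recorded.
#'
#' @param features list of [feature_column()]
#' @param impute "median" (numeric) / mode (nominal) — the only strategy
#'   currently provided
#' @return an object of class `feature_matrix`: list(X, dim_names,
#'   scaling) where X is compounds x dims with no missing/non-finite
#'   entries
#' @export
preprocess_features <- function(features, impute = "median") {
  stopifnot(length(features) >= 1)
  impute <- match.arg(impute)
  n <- length(features[[1]]$values)
  if (n < 2) stop("need at least 2 compounds")
  cols <- list(); dim_names <- character(0); scaling <- list()
  for (f in features) {
    if (f$ftype == "numeric") {
      v <- f$values
      if (all(is.na(v))) { warning("column '", f$name, "' all missing; dropped"); next }
      med <- stats::median(v, na.rm = TRUE)
      v[is.na(v)] <- med
      s <- sqrt(mean((v - mean(v))^2))  # population sd
      if (!is.finite(s) || s == 0) {
        warning("zero-variance column '", f$name, "' dropped")
        next
      }
      ctr <- mean(v)
      cols[[length(cols) + 1L]] <- (v - ctr) / s
      dim_names <- c(dim_names, f$name)
      scaling[[f$name]] <- list(type = "zscore", center = ctr, scale = s)
    } else {
      v <- f$values
      if (all(is.na(v))) { warning("column '", f$name, "' all missing; dropped"); next }
      tab <- table(v[!is.na(v)])
      mode_val <- names(tab)[which.max(tab)]
      v[is.na(v)] <- mode_val
      levels <- unique(v)
      if (length(levels) < 2) {
        warning("zero-variance column '", f$name, "' dropped")
        next
      }
      dummies <- vapply(levels, function(l) as.numeric(v == l), numeric(n))
      popvar <- function(x) mean((x - mean(x))^2)
      s <- 1 / sqrt(sum(apply(dummies, 2, popvar)))
      for (li in seq_along(levels)) {
        cols[[length(cols) + 1L]] <- dummies[, li] * s
        dim_names <- c(dim_names, paste0(f$name, "=", levels[li]))
      }
      scaling[[f$name]] <- list(type = "onehot", levels = levels, scale = s)
    }
  }
  if (!length(cols)) stop("no informative features")
  X <- do.call(cbind, cols)
  colnames(X) <- dim_names
  structure(list(X = X, dim_names = dim_names, scaling = scaling),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d compounds x %d dims\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

.as_matrix <- function(M) {
  if (inherits(M, "feature_matrix")) M$X else as.matrix(M)
}

.new_cluster_result <- function(labels, algorithm, params = list(),
                                quality_by_k = NULL, seed = NULL) {
  labels <- as.integer(labels)
  structure(list(labels = labels, k = length(unique(labels)),
                 algorithm = algorithm, params = params,
                 quality_by_k = quality_by_k, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s: k = %d over %d compounds\n",
              x$algorithm, x$k, length(x$labels)))
  if (!is.null(x$quality_by_k)) {
    cat("  Calinski-Harabasz by k:\n")
    print(round(x$quality_by_k, 3))
  }
  invisible(x)
}

.wss <- function(X, labels) {
  sum(vapply(split(seq_len(nrow(X)), labels), function(idx) {
    ctr <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, ctr)^2)
  }, numeric(1)))
}

.sq_dist_to_centers <- function(X, centers) {
  # n x k matrix of squared Euclidean distances
  xs <- rowSums(X^2)
  cs <- rowSums(centers^2)
  outer(xs, cs, "+") - 2 * X %*% t(centers)
}

.lloyd_once <- function(X, k, init_idx) {
  centers <- X[init_idx, , drop = FALSE]
  labels <- integer(nrow(X))
  prev_wss <- Inf
  repeat {
    D2 <- .sq_dist_to_centers(X, centers)
    labels <- max.col(-D2, ties.method = "first")
    # empty cluster: re-seed at the point farthest from its own centroid
    dvec <- D2[cbind(seq_len(nrow(X)), labels)]
    reseeded <- FALSE
    for (c in seq_len(k)) {
      if (any(labels == c)) next
      far <- which.max(dvec)
      labels[far] <- c
      dvec[far] <- -Inf
      reseeded <- TRUE
    }
    new_centers <- t(vapply(seq_len(k), function(c)
      colMeans(X[labels == c, , drop = FALSE]), numeric(ncol(X))))
    if (ncol(X) == 1L) new_centers <- matrix(new_centers, ncol = 1L)
    wss <- .wss(X, labels)
    if (!reseeded && wss > prev_wss + 1e-9)
      stop("internal error: k-means objective increased")
    shift <- max(rowSums((new_centers - centers)^2))
    centers <- new_centers
    if (shift < 1e-18 || abs(prev_wss - wss) < 1e-12 * max(1, wss)) break
    prev_wss <- wss
  }
  list(labels = labels, wss = .wss(X, labels))
}

#' Lloyd k-means with random restarts
#'
#' @param M a `feature_matrix` or numeric matrix
#' @param k number of clusters (1..n)
#' @param restarts random initialisations; the run with the lowest
#'   within-cluster sum of squares wins
#' @param seed integer seed (deterministic)
#' @return a `cluster_result`
#' @export
kmeans_cluster <- function(M, k, restarts = 10L, seed = 1L) {
  X <- .as_matrix(M)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be between 1 and the number of compounds")
  if (k == 1)
    return(.new_cluster_result(rep(1L, n), "kmeans",
                               list(k = 1, restarts = restarts), seed = seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- .lloyd_once(X, k, sample(n, k))
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  .new_cluster_result(best$labels, "kmeans",
                      list(k = k, restarts = restarts, wss = best$wss),
                      seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Calinski-Harabasz criterion
#'
#' `CH = (B / (k - 1)) / (W / (n - k))` with B the between-cluster sum of
#' squares about the global centroid and W the total within-cluster sum
#' of squares. A perfect partition with W = 0 and B > 0 returns `Inf`.
#'
#' @param M a `feature_matrix` or numeric matrix
#' @param labels cluster labels (2 <= k <= n - 1)
#' @return numeric score
#' @export
calinski_harabasz <- function(M, labels) {
  X <- .as_matrix(M)
  n <- nrow(X)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  if (k < 2 || k >= n)
    stop("Calinski-Harabasz is undefined for k < 2 or k >= n")
  global <- colMeans(X)
  W <- .wss(X, labels)
  B <- sum(vapply(split(seq_len(n), labels), function(idx) {
    ctr <- colMeans(X[idx, , drop = FALSE])
    length(idx) * sum((ctr - global)^2)
  }, numeric(1)))
  if (W == 0) return(if (B > 0) Inf else NaN)
  (B / (k - 1)) / (W / (n - k))
}

#' Cascade k-means with automatic selection of k
#'
#' Runs restarted k-means for every k in `[k_min, k_max]`, scores each
#' partition with the Calinski-Harabasz criterion and returns the best k
#' (ties broken toward smaller k). `quality_by_k` records all scores so
#' weak cluster structure stays visible to the caller.
#'
#' @param M a `feature_matrix` or numeric matrix
#' @param k_min,k_max candidate range (k_max clamped to n - 1 with a
#'   warning if it exceeds it)
#' @param restarts random restarts per k
#' @param seed integer seed
#' @return a `cluster_result` with `quality_by_k`
#' @export
cascade_kmeans <- function(M, k_min = 2L, k_max = NULL, restarts = 10L,
                           seed = 1L) {
  X <- .as_matrix(M)
  n <- nrow(X)
  if (n < 3) stop("cascade k-means needs at least 3 compounds")
  if (is.null(k_max)) k_max <- min(10L, ceiling(n / 2), n - 1L)
  if (k_max > n - 1L) {
    warning("k_max clamped to n - 1 = ", n - 1L)
    k_max <- n - 1L
  }
  if (k_min < 2L) stop("k_min must be >= 2 (criterion undefined at k = 1)")
  if (k_min > k_max) stop("k_min exceeds k_max")
  ks <- seq.int(k_min, k_max)
  scores <- numeric(length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    fits[[i]] <- kmeans_cluster(X, ks[i], restarts = restarts,
                                seed = seed + ks[i])
    scores[i] <- calinski_harabasz(X, fits[[i]]$labels)
  }
  best <- which.max(scores)  # first maximum = smallest k on ties
  res <- fits[[best]]
  res$algorithm <- "cascade-kmeans"
  res$params <- list(k_min = k_min, k_max = k_max, restarts = restarts)
  res$quality_by_k <- stats::setNames(scores, ks)
  res$seed <- seed
  res
}

#' Agglomerative hierarchical clustering
#'
#' Builds the merge tree from the Euclidean distance matrix under the
#' chosen linkage and cuts it to k clusters.
#'
#' @param M a `feature_matrix` or numeric matrix
#' @param linkage "single", "complete", "average" or "ward"
#' @param k number of clusters
#' @return a `cluster_result`
#' @export
hierarchical_cluster <- function(M, linkage = "complete", k) {
  X <- .as_matrix(M)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be between 1 and the number of compounds")
  method <- switch(linkage, single = "single", complete = "complete",
                   average = "average", ward = "ward.D2",
                   stop("invalid linkage '", linkage,
                        "'; use single|complete|average|ward"))
  tree <- stats::hclust(stats::dist(X), method = method)
  labels <- stats::cutree(tree, k = k)
  .new_cluster_result(labels, "hierarchical",
                      list(linkage = linkage, k = k))
}

#' Farthest-first traversal clustering
#'
#' The first centre is a uniformly random point (seeded); each further
#' centre maximises the distance to its nearest already-chosen centre;
#' points are then assigned to the nearest centre.
#'
#' @param M a `feature_matrix` or numeric matrix
#' @param k number of clusters
#' @param seed integer seed
#' @return a `cluster_result`
#' @export
farthest_first <- function(M, k, seed = 1L) {
  X <- .as_matrix(M)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be between 1 and the number of compounds")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  centers <- sample(n, 1L)
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
    while (length(centers) < k) {
      nxt <- which.max(d2)
      centers <- c(centers, nxt)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[nxt, ])^2))
    }
  }
  D2 <- .sq_dist_to_centers(X, X[centers, , drop = FALSE])
  labels <- max.col(-D2, ties.method = "first")
  .new_cluster_result(labels, "farthest-first",
                      list(k = k, centers = centers), seed = seed)
}

#' The no-clustering option
#'
#' Places all compounds in a single cluster (the only viable choice when
#' no features are selected); downstream alignment treats the whole set
#' as one cluster.
#'
#' @param n number of compounds
#' @return a `cluster_result` with `algorithm = "none"`, k = 1
#' @export
no_clustering <- function(n) {
  stopifnot(n >= 1)
  .new_cluster_result(rep(1L, n), "none")
}
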